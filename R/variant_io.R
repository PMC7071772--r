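# Reading, validating and filtering variant input.
#
# Coordinates are 0-based half-open internally (BED convention); VCF
# positions are converted at the boundary.

#' Read gene regions from a BED file
#'
#' Parses a BED3+ file into a region catalog. BED coordinates are already
#' 0-based half-open, which is the internal convention, so no shifting is
#' performed. The optional fourth column supplies the region (gene) name;
#' unnamed regions get a `chrom:start-end` label.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tNPPA", bed)
#' read_regions(bed)
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  regions <- lapply(seq_along(idx), function(k) {
    f <- fields[[k]]
    ln <- idx[k]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d: expected >= 3 tab-separated fields", ln))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed BED line %d: non-numeric coordinates", ln))
    }
    if (!nzchar(f[1])) stop(sprintf("malformed BED line %d: empty chromosome", ln))
    if (start >= end) {
      stop(sprintf("invalid region on BED line %d: start (%d) must be < end (%d)",
                   ln, start, end))
    }
    name <- if (length(f) >= 4L && nzchar(f[4])) f[4] else
      sprintf("%s:%d-%d", f[1], start, end)
    data.frame(name = name, chrom = f[1], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  if (anyDuplicated(out$name)) {
    stop("duplicate region names in catalog: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

.strip_chr <- function(x) sub("^chr", "", x)

# Split raw INFO strings once into key=value lists.
.split_info <- function(info) {
  strsplit(ifelse(is.na(info), "", info), ";", fixed = TRUE)
}

.info_field <- function(info_split, key) {
  prefix <- paste0(key, "=")
  vapply(info_split, function(kv) {
    hit <- kv[startsWith(kv, prefix)]
    if (length(hit)) substring(hit[1], nchar(prefix) + 1L) else NA_character_
  }, character(1))
}

# Tally alt-allele and total called-allele counts from a GT matrix
# (variants x samples) for one set of sample names.
.tally_gt <- function(gt, samples) {
  sub <- gt[, intersect(samples, colnames(gt)), drop = FALSE]
  ac <- integer(nrow(sub))
  an <- integer(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    g <- sub[i, ]
    g <- g[!is.na(g)]
    al <- unlist(strsplit(g, "[|/]"))
    al <- al[al != "."]
    ac[i] <- sum(al == "1")
    an[i] <- length(al)
  }
  list(ac = ac, an = an)
}

#' Read variant sites from a VCF restricted to gene regions
#'
#' Loads a VCF (plain or bgzipped), keeps only records whose 1-based
#' position falls inside one of the supplied regions, and extracts
#' per-population allele counts. Counts come from gnomAD-style
#' `AC_<code>`/`AN_<code>` INFO fields when present; otherwise they are
#' tallied from sample genotypes using a sample-to-population map. The
#' ancestral-allele `AA` INFO tag is captured verbatim when present.
#'
#' @param path Path to a VCF file.
#' @param regions Region catalog from [read_regions()] (0-based half-open).
#' @param pop_codes Character vector of population codes to extract counts
#'   for (e.g. `c("afr", "nfe")`).
#' @param sample_map Optional two-column `data.frame` (or path to a
#'   headerless two-column TSV) mapping sample id to population code; used
#'   to tally counts from genotypes when INFO count fields are absent.
#' @param normalize_chr If `TRUE` (default), an optional `"chr"` prefix is
#'   stripped from both VCF and region chromosome labels before matching.
#' @return A `data.frame` of variant sites with columns `chrom`, `pos`
#'   (1-based), `id`, `ref`, `alt` (comma-separated for multiallelic
#'   records), `aa`, and numeric `ac_<code>`/`an_<code>` pairs. For
#'   multiallelic records the first alt's AC is reported; such records are
#'   removed by [filter_biallelic_snps()] before any frequency work.
#' @export
read_variants <- function(path, regions, pop_codes, sample_map = NULL,
                          normalize_chr = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (length(pop_codes) == 0L) stop("pop_codes must be non-empty")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    return(.empty_sites(pop_codes))
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  rchrom <- regions$chrom
  if (normalize_chr) {
    chrom_m <- .strip_chr(chrom)
    rchrom <- .strip_chr(rchrom)
  } else {
    chrom_m <- chrom
  }
  inside <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(regions))) {
    inside <- inside |
      (chrom_m == rchrom[r] & pos > regions$start[r] & pos <= regions$end[r])
  }
  if (!any(inside)) return(.empty_sites(pop_codes))

  fix <- fix[inside, , drop = FALSE]
  info_split <- .split_info(fix[, "INFO"])
  out <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    aa = .info_field(info_split, "AA"),
    stringsAsFactors = FALSE
  )

  have_info_counts <- all(vapply(pop_codes, function(code) {
    any(!is.na(.info_field(info_split, paste0("AC_", code))))
  }, logical(1)))

  if (have_info_counts) {
    for (code in pop_codes) {
      ac_raw <- .info_field(info_split, paste0("AC_", code))
      an_raw <- .info_field(info_split, paste0("AN_", code))
      # multiallelic AC fields are comma-separated per alt; keep the first
      ac1 <- sub(",.*$", "", ac_raw)
      out[[paste0("ac_", code)]] <- suppressWarnings(as.numeric(ac1))
      out[[paste0("an_", code)]] <- suppressWarnings(as.numeric(an_raw))
    }
  } else {
    gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                   error = function(e) NULL)
    if (is.null(gt) || is.null(sample_map)) {
      stop("VCF lacks AC_/AN_ INFO fields for the requested populations ",
           "and no genotypes + sample_map are available to tally counts")
    }
    if (is.character(sample_map)) {
      sample_map <- utils::read.table(sample_map, sep = "\t", header = FALSE,
                                      col.names = c("sample", "pop"),
                                      stringsAsFactors = FALSE)
    }
    gt <- gt[inside, , drop = FALSE]
    for (code in pop_codes) {
      samples <- sample_map$sample[sample_map$pop == code]
      if (length(samples) == 0L) {
        stop("sample_map contains no samples for population '", code, "'")
      }
      counts <- .tally_gt(gt, samples)
      out[[paste0("ac_", code)]] <- counts$ac
      out[[paste0("an_", code)]] <- counts$an
    }
  }
  rownames(out) <- NULL
  out
}

.empty_sites <- function(pop_codes) {
  out <- data.frame(chrom = character(), pos = integer(), id = character(),
                    ref = character(), alt = character(), aa = character(),
                    stringsAsFactors = FALSE)
  for (code in pop_codes) {
    out[[paste0("ac_", code)]] <- numeric()
    out[[paste0("an_", code)]] <- numeric()
  }
  out
}

#' Separate biallelic SNPs from indels and multiallelic records
#'
#' Multiallelic records (more than one alt allele) are dropped whole rather
#' than split, because polarization into a single derived allele is only
#' defined for biallelic sites; they are counted separately from indels so
#' the removal report stays auditable.
#'
#' @param sites Variant `data.frame` from [read_variants()].
#' @return A list with `snps` (retained biallelic SNPs), `n_removed_indels`
#'   and `n_removed_multiallelic`. The conservation identity
#'   `nrow(sites) == nrow(snps) + n_removed_indels + n_removed_multiallelic`
#'   always holds.
#' @export
filter_biallelic_snps <- function(sites) {
  n_alts <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  multi <- n_alts > 1L
  snv <- !multi & nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
  indel <- !multi & !snv
  list(
    snps = sites[snv, , drop = FALSE],
    n_removed_indels = sum(indel),
    n_removed_multiallelic = sum(multi)
  )
}

#' Write variant sites back to a sites-only VCF
#'
#' Emits a minimal VCF v4.2 with `AA` and `AC_<code>`/`AN_<code>` INFO
#' fields. Re-reading the file through [read_variants()] reproduces
#' positions, alleles and per-population counts exactly.
#'
#' @param sites Variant `data.frame` as returned by [read_variants()].
#' @param path Output path.
#' @param header_extra Optional character vector of extra `##` header lines
#'   (e.g. a simulation seed record).
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path, header_extra = NULL) {
  codes <- sub("^ac_", "", grep("^ac_", names(sites), value = TRUE))
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    unlist(lapply(codes, function(code) c(
      sprintf('##INFO=<ID=AC_%s,Number=A,Type=Integer,Description="Alt allele count (%s)">',
              code, code),
      sprintf('##INFO=<ID=AN_%s,Number=1,Type=Integer,Description="Called alleles (%s)">',
              code, code)
    ))),
    header_extra,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(sites)), function(i) {
    parts <- character(0)
    if (!is.na(sites$aa[i])) parts <- c(parts, paste0("AA=", sites$aa[i]))
    for (code in codes) {
      ac <- sites[[paste0("ac_", code)]][i]
      an <- sites[[paste0("an_", code)]][i]
      parts <- c(parts,
                 paste0("AC_", code, "=", format(ac, scientific = FALSE)),
                 paste0("AN_", code, "=", format(an, scientific = FALSE)))
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  body <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
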