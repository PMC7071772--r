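# Ancestral-allele assignment and ref/alt -> ancestral/derived polarization.

#' Read a primate-allele table
#'
#' Outgroup alleles used as the polarization fallback when a SNP carries no
#' ancestral-allele annotation. One row per (site, species).
#'
#' @param path Tab-separated file with columns chrom, pos (1-based),
#'   species, allele. A header line is accepted and detected.
#' @return `data.frame` with columns `chrom`, `pos`, `species`, `allele`.
#' @export
read_primate_alleles <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "species", "allele"))
  df$pos <- as.integer(df$pos)
  df$allele <- toupper(df$allele)
  df
}

# Clean a raw AA INFO value: strip Ensembl-style qualifier fields after
# "|", optionally accept lower-case (low-confidence) calls.
.clean_aa <- function(aa, accept_lowercase = TRUE) {
  aa <- sub("\\|.*$", "", aa)
  if (accept_lowercase) aa <- toupper(aa)
  aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_
  aa
}

#' Assign ancestral alleles to biallelic SNPs
#'
#' Annotation-first rule: a valid `AA` tag matching ref or alt wins; for
#' the remaining sites the strict-majority allele among non-missing primate
#' outgroup alleles is used, provided it is supported by at least
#' `min_species` species and matches ref or alt; otherwise the site is
#' left unassigned. An AA tag naming a third allele is logged and falls
#' through to the primate consensus rather than erroring.
#'
#' @param snps Biallelic SNP `data.frame` (see [filter_biallelic_snps()]).
#' @param primate_alleles Optional table from [read_primate_alleles()].
#' @param min_species Minimum number of species supporting the majority
#'   allele for a primate-consensus call (default 2).
#' @param accept_lowercase Accept lower-case (low-confidence) AA tags
#'   (default `TRUE`).
#' @return `data.frame` with one row per input SNP: `allele` (A/C/G/T or
#'   `NA`) and `source` (`"annotation"`, `"primate_consensus"`, or
#'   `"unassigned"`).
#' @export
assign_ancestral <- function(snps, primate_alleles = NULL, min_species = 2L,
                             accept_lowercase = TRUE) {
  n <- nrow(snps)
  allele <- rep(NA_character_, n)
  source <- rep("unassigned", n)

  aa <- .clean_aa(snps$aa, accept_lowercase = accept_lowercase)
  ok <- !is.na(aa) & (aa == snps$ref | aa == snps$alt)
  allele[ok] <- aa[ok]
  source[ok] <- "annotation"
  mismatch <- !is.na(aa) & !ok
  if (any(mismatch)) {
    message(sum(mismatch), " AA tag(s) named an allele outside {ref, alt}; ",
            "falling through to primate consensus")
  }

  need <- which(!ok)
  if (length(need) && !is.null(primate_alleles) && nrow(primate_alleles)) {
    key <- paste(snps$chrom, snps$pos)
    pkey <- paste(primate_alleles$chrom, primate_alleles$pos)
    split_alleles <- split(primate_alleles$allele, pkey)
    for (i in need) {
      al <- split_alleles[[key[i]]]
      al <- al[al %in% c("A", "C", "G", "T")]
      if (length(al) == 0L) next
      tab <- sort(table(al), decreasing = TRUE)
      # strict majority: top count unique and meets the species floor
      if (tab[1] < min_species) next
      if (length(tab) > 1L && tab[2] == tab[1]) next
      cand <- names(tab)[1]
      if (cand == snps$ref[i] || cand == snps$alt[i]) {
        allele[i] <- cand
        source[i] <- "primate_consensus"
      }
    }
  }
  data.frame(allele = allele, source = source, stringsAsFactors = FALSE)
}

#' Polarize SNPs into ancestral/derived orientation
#'
#' For each SNP with an ancestral call, the derived allele is the member of
#' \{ref, alt\} that is not ancestral, and per-population derived allele
#' frequencies are computed: `AC/AN` when the derived allele is alt, and
#' `(AN - AC)/AN` when it is ref. Frequencies are `NA` where `AN = 0`.
#' SNPs without an ancestral call are returned in an exclusion table with
#' a reason instead of being silently dropped, so variant accounting sums.
#'
#' @param snps Biallelic SNP `data.frame`.
#' @param calls Ancestral calls from [assign_ancestral()], row-aligned
#'   with `snps`.
#' @return A list with `polarized` (columns of `snps` plus `ancestral`,
#'   `derived`, `anc_source`, and `dac_<code>`/`daf_<code>` per population)
#'   and `excluded` (`id`, `chrom`, `pos`, `reason`).
#' @export
polarize <- function(snps, calls) {
  stopifnot(nrow(snps) == nrow(calls))
  keep <- calls$source != "unassigned"
  excluded <- data.frame(
    id = snps$id[!keep], chrom = snps$chrom[!keep], pos = snps$pos[!keep],
    reason = rep("no_ancestral_call", sum(!keep)),
    stringsAsFactors = FALSE
  )
  pol <- snps[keep, , drop = FALSE]
  anc <- calls$allele[keep]
  pol$ancestral <- anc
  pol$derived <- ifelse(anc == pol$ref, pol$alt, pol$ref)
  pol$anc_source <- calls$source[keep]
  codes <- sub("^ac_", "", grep("^ac_", names(snps), value = TRUE))
  flip <- pol$derived == pol$ref
  for (code in codes) {
    ac <- pol[[paste0("ac_", code)]]
    an <- pol[[paste0("an_", code)]]
    dac <- ifelse(flip, an - ac, ac)
    pol[[paste0("dac_", code)]] <- dac
    pol[[paste0("daf_", code)]] <- ifelse(an > 0, dac / an, NA_real_)
  }
  rownames(pol) <- NULL
  list(polarized = pol, excluded = excluded)
}
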