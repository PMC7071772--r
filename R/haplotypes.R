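# Phased haplotype matrices: construction, VCF import, derived-allele
# orientation.

#' Construct a phased haplotype matrix
#'
#' Rows are phased haplotypes (two per diploid sample), columns are sites
#' in genomic order; entries are 1 for the derived (or alt, if not yet
#' polarized) allele.
#'
#' @param mat 0/1 matrix, haplotypes x sites.
#' @param site_ids Character vector of site ids (one per column).
#' @param positions Integer 1-based positions, strictly increasing.
#' @param pop_labels Population code per row.
#' @return Object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(mat, site_ids, positions, pop_labels) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("haplotype entries must be 0 or 1")
  if (ncol(mat) != length(site_ids) || ncol(mat) != length(positions)) {
    stop("site_ids and positions must match the number of columns")
  }
  if (nrow(mat) != length(pop_labels)) {
    stop("pop_labels must match the number of rows")
  }
  if (nrow(mat) %% 2L != 0L) {
    stop("row count must be even (two phased haplotypes per diploid)")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing (genomic order)")
  }
  structure(list(mat = mat, site_ids = as.character(site_ids),
                 positions = as.integer(positions),
                 pop_labels = as.character(pop_labels)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites (%s)\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s=%d", names(table(x$pop_labels)),
                            table(x$pop_labels)), collapse = ", ")))
  invisible(x)
}

#' Read phased haplotypes from a VCF with genotypes
#'
#' Extracts phased GT fields for biallelic SNPs into a
#' [haplotype_matrix()], two rows per sample. When a polarized table is
#' supplied, columns whose derived allele is the reference are flipped so
#' that 1 always means derived; otherwise 1 means alt.
#'
#' @param path VCF path (must contain sample genotypes, phased with `|`).
#' @param sample_map Two-column `data.frame` or TSV path (sample, pop).
#' @param polarized Optional polarized table from [polarize()] with
#'   `chrom`, `pos`, `derived`, `ref` columns.
#' @param pops Optional subset of population codes to keep.
#' @return A [haplotype_matrix()].
#' @export
read_haplotypes <- function(path, sample_map, polarized = NULL, pops = NULL) {
  if (is.character(sample_map)) {
    sample_map <- utils::read.table(sample_map, sep = "\t", header = FALSE,
                                    col.names = c("sample", "pop"),
                                    stringsAsFactors = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  bial <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(vcf, element = "GT")[bial, , drop = FALSE]
  fix <- fix[bial, , drop = FALSE]
  samples <- colnames(gt)
  pop <- sample_map$pop[match(samples, sample_map$sample)]
  keep_s <- !is.na(pop)
  if (!is.null(pops)) keep_s <- keep_s & pop %in% pops
  gt <- gt[, keep_s, drop = FALSE]
  pop <- pop[keep_s]
  if (ncol(gt) == 0L) stop("no samples matched the sample map / populations")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes found; haplotype extraction needs phased '|' GT")
  }
  n_sites <- nrow(gt)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = ncol(gt),
               ncol = n_sites, byrow = TRUE)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = ncol(gt),
               ncol = n_sites, byrow = TRUE)
  mat <- matrix(0L, nrow = 2L * ncol(gt), ncol = n_sites)
  mat[seq(1, nrow(mat), by = 2), ] <- h1
  mat[seq(2, nrow(mat), by = 2), ] <- h2
  pop_labels <- rep(pop, each = 2L)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  positions <- as.integer(fix[, "POS"])
  if (!is.null(polarized)) {
    key <- paste(fix[, "CHROM"], fix[, "POS"])
    pkey <- paste(polarized$chrom, polarized$pos)
    m <- match(key, pkey)
    flip <- !is.na(m) & polarized$derived[m] == polarized$ref[m]
    mat[, flip] <- 1L - mat[, flip]
  }
  ord <- order(positions)
  haplotype_matrix(mat[, ord, drop = FALSE], ids[ord], positions[ord],
                   pop_labels)
}
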