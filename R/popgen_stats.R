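# Per-site FST, pairwise LD r2 from phased haplotypes, and LD-bounded
# window selection around a focal SNP.

#' Per-site FST between two populations
#'
#' Computes per-site FST from derived-allele counts in two populations.
#' Two estimators are available:
#'
#' * `"hudson"`: \eqn{[(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)]
#'   / [p_1(1-p_2) + p_2(1-p_1)]} with \eqn{n} the number of called alleles.
#' * `"weir_cockerham"` (default): the two-population per-site
#'   variance-components estimator \eqn{a/(a+b+c)}, with the heterozygote
#'   frequency taken at its Hardy-Weinberg expectation
#'   \eqn{h_i = 2 p_i (1-p_i)} since only allele counts (not genotypes)
#'   are available.
#'
#' Estimates can be negative in finite samples and are reported as-is,
#' not clamped. The value is `NA` where the denominator is zero (both
#' populations monomorphic for the same allele).
#'
#' @param dac_a,an_a Derived count and total called alleles in population
#'   a (vectorized over sites).
#' @param dac_b,an_b Same for population b.
#' @param estimator `"weir_cockerham"` or `"hudson"`.
#' @return Numeric vector of FST values with the estimator name in
#'   `attr(, "estimator")`.
#' @export
site_fst <- function(dac_a, an_a, dac_b, an_b,
                     estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  if (any(an_a < 2 | an_b < 2)) {
    stop("site_fst needs at least 2 called alleles in each population")
  }
  p1 <- dac_a / an_a
  p2 <- dac_b / an_b
  fst <- if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (an_a - 1) - p2 * (1 - p2) / (an_b - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ifelse(den > 0, num / den, NA_real_)
  } else {
    .fst_wc2(p1, an_a / 2, p2, an_b / 2)
  }
  attr(fst, "estimator") <- estimator
  fst
}

# Weir & Cockerham (1984) two-population per-site estimator, diploid
# variance components a/(a+b+c); heterozygosity at HWE expectation.
.fst_wc2 <- function(p1, n1, p2, n2) {
  r <- 2
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  ifelse(abs(den) > 0, a / den, NA_real_)
}

#' Pairwise LD r-squared between two sites on phased haplotypes
#'
#' \eqn{r^2 = D^2 / [p_A(1-p_A) p_B(1-p_B)]} with
#' \eqn{D = p_{AB} - p_A p_B}, computed from haplotype counts. Undefined
#' (`NA`) when either site is monomorphic in the sample used.
#'
#' @param col_i,col_j Equal-length 0/1 vectors (one entry per phased
#'   haplotype; no missing values).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(col_i, col_j) {
  if (length(col_i) != length(col_j)) stop("columns must have equal length")
  if (length(col_i) < 2L) stop("need at least 2 haplotypes")
  if (anyNA(col_i) || anyNA(col_j) ||
      !all(col_i %in% c(0, 1)) || !all(col_j %in% c(0, 1))) {
    stop("columns must be 0/1 with no missing entries (phased haplotypes)")
  }
  pA <- mean(col_i)
  pB <- mean(col_j)
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  D <- mean(col_i * col_j) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Long-format pairwise LD table for a haplotype matrix
#'
#' @param haps A [haplotype_matrix()].
#' @param sites Optional site ids or column indices to restrict to.
#' @param pops Optional population codes: LD is computed on the haplotypes
#'   of these populations only (the `pop_set` column records which).
#' @return `data.frame` with `id_i`, `id_j`, `pop_set`, `r2` for all
#'   unordered site pairs.
#' @export
ld_table <- function(haps, sites = NULL, pops = NULL) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  mat <- haps$mat
  ids <- haps$site_ids
  if (!is.null(sites)) {
    idx <- if (is.numeric(sites)) sites else match(sites, ids)
    if (anyNA(idx)) stop("unknown site id(s) requested")
    mat <- mat[, idx, drop = FALSE]
    ids <- ids[idx]
  }
  pop_set <- "all"
  if (!is.null(pops)) {
    mat <- mat[haps$pop_labels %in% pops, , drop = FALSE]
    pop_set <- paste(pops, collapse = "+")
  }
  n <- length(ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    ld_r2(mat[, pairs[k, 1]], mat[, pairs[k, 2]])
  }, numeric(1))
  data.frame(id_i = ids[pairs[, 1]], id_j = ids[pairs[, 2]],
             pop_set = pop_set, r2 = r2, stringsAsFactors = FALSE)
}

#' Select an LD-bounded window around a focal SNP
#'
#' Scanning outward from the focal site on each flank, the window boundary
#' is the outermost site whose r-squared with the focal SNP exceeds
#' `r2_max`; sites beyond it are in low LD with the focal SNP and are
#' trimmed. If no flanking site exceeds `r2_max` on a side, the window
#' ends at the focal site on that side, so the window always contains the
#' focal SNP.
#'
#' @param haps A [haplotype_matrix()].
#' @param focal Focal site id (or column index).
#' @param r2_max LD bound (default 0.2).
#' @return List with `start`, `end` (column indices), `site_ids`,
#'   `span_bp`, `n_sites`, and the focal-vs-site `r2` profile.
#' @export
select_window <- function(haps, focal, r2_max = 0.2) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  f <- if (is.numeric(focal)) focal else match(focal, haps$site_ids)
  if (is.na(f) || f < 1 || f > ncol(haps$mat)) stop("focal site not found")
  fc <- haps$mat[, f]
  if (all(fc == fc[1])) {
    stop("focal site is monomorphic; r2 is undefined against every site")
  }
  n <- ncol(haps$mat)
  r2 <- vapply(seq_len(n), function(j) {
    if (j == f) return(1)
    ld_r2(fc, haps$mat[, j])
  }, numeric(1))
  exceeds <- !is.na(r2) & r2 > r2_max
  left <- which(exceeds[seq_len(f - 1)])
  right <- which(exceeds[seq(f + 1, length.out = n - f)]) + f
  lo <- if (length(left)) min(left) else f
  hi <- if (length(right)) max(right) else f
  list(start = lo, end = hi,
       site_ids = haps$site_ids[lo:hi],
       span_bp = haps$positions[hi] - haps$positions[lo] + 1L,
       n_sites = hi - lo + 1L,
       r2 = r2)
}
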