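# Pooling derived allele frequencies into two groups, the delta-DAF
# statistic, its distribution, and outlier selection.

#' Define a two-group population grouping
#'
#' @param a_label,b_label Group display labels (e.g. `"African"`,
#'   `"non-African"`).
#' @param a_codes,b_codes Non-empty, disjoint character vectors of
#'   population codes assigned to each group.
#' @return A list of class `pop_grouping`.
#' @export
population_grouping <- function(a_label, a_codes, b_label, b_codes) {
  if (length(a_codes) == 0L || length(b_codes) == 0L) {
    stop("both groups need at least one population code")
  }
  if (length(intersect(a_codes, b_codes)) > 0L) {
    stop("population codes must be disjoint between groups: ",
         paste(intersect(a_codes, b_codes), collapse = ", "))
  }
  structure(list(a_label = a_label, a_codes = a_codes,
                 b_label = b_label, b_codes = b_codes),
            class = "pop_grouping")
}

#' Pool derived allele counts into one frequency
#'
#' Allele-count weighting: the pooled frequency is the sum of derived
#' counts divided by the sum of called alleles, which equals the derived
#' allele frequency in the pooled sample. Populations with `AN = 0`
#' contribute nothing; if all populations have `AN = 0` the frequency is
#' undefined (`NA`). With `weighting = "mean"` the unweighted mean of the
#' defined per-population frequencies is returned instead (sensitivity
#' mode).
#'
#' @param dac Numeric vector (one site, populations) or matrix (sites x
#'   populations) of derived allele counts.
#' @param an Matching vector/matrix of total called alleles.
#' @param weighting `"count"` (default) or `"mean"`.
#' @return Pooled frequency (vector over sites for matrix input).
#' @examples
#' pooled_daf(c(10, 150), c(100, 300))  # 160/400 = 0.4, not mean(0.1, 0.5)
#' @export
pooled_daf <- function(dac, an, weighting = c("count", "mean")) {
  weighting <- match.arg(weighting)
  if (is.null(dim(dac))) dac <- matrix(dac, nrow = 1L)
  if (is.null(dim(an))) an <- matrix(an, nrow = 1L)
  stopifnot(all(dim(dac) == dim(an)))
  if (any(dac > an, na.rm = TRUE) || any(dac < 0, na.rm = TRUE)) {
    stop("derived counts must satisfy 0 <= dac <= an")
  }
  if (weighting == "count") {
    tot_an <- rowSums(an)
    out <- ifelse(tot_an > 0, rowSums(dac) / tot_an, NA_real_)
  } else {
    freq <- ifelse(an > 0, dac / an, NA_real_)
    out <- rowMeans(freq, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
  }
  out
}

#' Absolute difference in derived allele frequency between two groups
#'
#' @param daf_a,daf_b Derived allele frequencies in `[0, 1]`.
#' @return `|daf_a - daf_b|`, vectorized.
#' @examples
#' delta_daf(0.1750, 0.4979)  # 0.3229
#' @export
delta_daf <- function(daf_a, daf_b) {
  if (any(daf_a < 0 | daf_a > 1 | daf_b < 0 | daf_b > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  abs(daf_a - daf_b)
}

#' Compute per-variant group DAFs and delta-DAF
#'
#' Pools the per-population derived counts of polarized SNPs into the two
#' groups of `grouping` and attaches the delta-DAF statistic. Variants for
#' which either group has no called alleles are dropped with a reason.
#'
#' @param polarized Polarized SNP table from [polarize()].
#' @param grouping A [population_grouping()].
#' @param weighting Pooling mode passed to [pooled_daf()].
#' @return List with `records` (columns `id`, `chrom`, `pos`, `ref`,
#'   `ancestral`, `derived`, `daf_a`, `daf_b`, `delta_daf`) and `dropped`
#'   (`id`, `reason`).
#' @export
daf_records <- function(polarized, grouping, weighting = c("count", "mean")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(grouping, "pop_grouping"))
  grab <- function(codes, prefix) {
    cols <- paste0(prefix, codes)
    missing <- setdiff(cols, names(polarized))
    if (length(missing)) stop("missing count columns: ",
                              paste(missing, collapse = ", "))
    as.matrix(polarized[, cols, drop = FALSE])
  }
  daf_a <- pooled_daf(grab(grouping$a_codes, "dac_"),
                      grab(grouping$a_codes, "an_"), weighting)
  daf_b <- pooled_daf(grab(grouping$b_codes, "dac_"),
                      grab(grouping$b_codes, "an_"), weighting)
  ok <- !is.na(daf_a) & !is.na(daf_b)
  records <- data.frame(
    id = polarized$id[ok], chrom = polarized$chrom[ok], pos = polarized$pos[ok],
    ref = polarized$ref[ok], ancestral = polarized$ancestral[ok],
    derived = polarized$derived[ok],
    daf_a = daf_a[ok], daf_b = daf_b[ok],
    delta_daf = delta_daf(daf_a[ok], daf_b[ok]),
    stringsAsFactors = FALSE
  )
  dropped <- data.frame(
    id = polarized$id[!ok],
    reason = rep("undefined_group_frequency", sum(!ok)),
    stringsAsFactors = FALSE
  )
  list(records = records, dropped = dropped)
}

# Inclusive nearest-rank empirical percentile.
.nearest_rank_percentile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

#' Select highly differentiated outlier SNPs
#'
#' In `fixed` mode the threshold is the supplied cutoff; in `percentile`
#' mode it is the empirical cutoff-th percentile of the delta-DAF values
#' (inclusive nearest-rank). Selection is inclusive: records with
#' `delta_daf >= threshold` are outliers, so ties at the threshold are all
#' selected.
#'
#' @param records Record table from [daf_records()] (or any `data.frame`
#'   with a `delta_daf` column).
#' @param mode `"fixed"` or `"percentile"`.
#' @param cutoff Threshold in `(0, 1]` (fixed) or percentile in `(0, 100)`.
#' @param bin_width Bin width for the delta-DAF histogram (default 0.05).
#' @return Object of class `daf_scan_result`: `records`, `threshold`,
#'   `mode`, `outliers` (sorted by decreasing delta-DAF), `histogram`.
#' @export
select_outliers <- function(records, mode = c("fixed", "percentile"), cutoff,
                            bin_width = 0.05) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("records must be non-empty")
  deltas <- records$delta_daf
  if (mode == "fixed") {
    if (cutoff <= 0 || cutoff > 1) stop("fixed cutoff must be in (0, 1]")
    threshold <- cutoff
  } else {
    if (cutoff <= 0 || cutoff >= 100) stop("percentile cutoff must be in (0, 100)")
    threshold <- .nearest_rank_percentile(deltas, cutoff)
  }
  outliers <- records[deltas >= threshold, , drop = FALSE]
  outliers <- outliers[order(-outliers$delta_daf, outliers$id), , drop = FALSE]
  rownames(outliers) <- NULL
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  structure(list(records = records, threshold = threshold, mode = mode,
                 cutoff = cutoff,
                 outliers = outliers,
                 histogram = bin_distribution(deltas, edges)),
            class = "daf_scan_result")
}

#' @export
print.daf_scan_result <- function(x, ...) {
  cat(sprintf("delta-DAF scan: %d records, %s threshold %.4f -> %d outliers\n",
              nrow(x$records), x$mode, x$threshold, nrow(x$outliers)))
  invisible(x)
}

#' Bin values in the unit interval into a histogram
#'
#' Bins are right-open except the last, which is closed, so 1.0 falls in
#' the final bin.
#'
#' @param values Numeric values in `[0, 1]`.
#' @param edges Strictly increasing bin edges covering `[0, 1]`.
#' @return `data.frame` with `lower`, `upper`, `count`, `proportion`
#'   (all-zero counts for empty input; proportions sum to 1 otherwise).
#' @export
bin_distribution <- function(values, edges) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (edges[1] > 0 || edges[length(edges)] < 1) {
    stop("edges must cover [0, 1]")
  }
  if (any(values < 0 | values > 1, na.rm = TRUE) || anyNA(values)) {
    stop("values must lie in [0, 1] with no missing entries")
  }
  nb <- length(edges) - 1L
  if (length(values)) {
    bin <- findInterval(values, edges, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = nb)
  } else {
    counts <- integer(nb)
  }
  n <- sum(counts)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = counts,
             proportion = if (n > 0) counts / n else rep(0, nb))
}
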