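# End-to-end scan and network drivers producing run reports whose every
# number is recomputable from the emitted intermediate tables.

#' Retained-SNP accounting identity
#'
#' @param total Total variable sites read.
#' @param indels Records removed as indels (or other non-SNVs).
#' @param multiallelic Records removed as multiallelic.
#' @return Number of SNPs retained, `total - indels - multiallelic`.
#' @examples
#' scan_accounting(769597, 125372)  # 644225
#' @export
scan_accounting <- function(total, indels, multiallelic = 0) {
  retained <- total - indels - multiallelic
  if (retained < 0) stop("removals exceed the total")
  retained
}

.write_report_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full differentiation scan
#'
#' Reads variants restricted to the gene regions, separates biallelic
#' SNPs, polarizes them (annotation-first, primate-consensus fallback),
#' pools derived allele frequencies into the two groups, selects
#' delta-DAF outliers and filters them by consequence severity. Writes an
#' accounting report, a ranked outlier table, the impactful-outlier
#' table, and delta-DAF / per-group DAF histograms under `out_dir`. All
#' outputs are deterministic for identical inputs.
#'
#' @param vcf,bed,primate,annotations Input file paths (annotations and
#'   primate may be `NULL`).
#' @param grouping A [population_grouping()].
#' @param out_dir Output directory.
#' @param mode,cutoff Outlier selection mode and cutoff (see
#'   [select_outliers()]).
#' @param weighting Group pooling mode (see [pooled_daf()]).
#' @param sample_map Optional sample-to-population map for genotype VCFs.
#' @param delta_bin,daf_bin Histogram bin widths (defaults 0.05 and 0.10).
#' @param estimator FST estimator name recorded in the report and used
#'   for the outlier FST column.
#' @return Invisible list: `sites`, `snps`, `polarized`, `excluded`,
#'   `records`, `scan`, `impactful`, `accounting`, `files`.
#' @export
run_scan <- function(vcf, bed, grouping, out_dir,
                     primate = NULL, annotations = NULL,
                     mode = "fixed", cutoff = 0.2,
                     weighting = "count", sample_map = NULL,
                     delta_bin = 0.05, daf_bin = 0.10,
                     estimator = "weir_cockerham") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  codes <- c(grouping$a_codes, grouping$b_codes)
  regions <- read_regions(bed)
  sites <- read_variants(vcf, regions, codes, sample_map = sample_map)
  filt <- filter_biallelic_snps(sites)
  primate_tab <- if (!is.null(primate)) read_primate_alleles(primate) else NULL
  calls <- assign_ancestral(filt$snps, primate_tab)
  pol <- polarize(filt$snps, calls)
  rec <- daf_records(pol$polarized, grouping, weighting = weighting)
  scan <- select_outliers(rec$records, mode = mode, cutoff = cutoff,
                          bin_width = delta_bin)

  if (!is.null(annotations)) {
    ann <- read_consequences(annotations)
    imp <- filter_impactful(ann, scan)
  } else {
    imp <- list(kept = data.frame(id = character(), delta_daf = numeric(),
                                  term = character(), impact = character()),
                missing = character())
  }

  accounting <- data.frame(
    metric = c("total_sites", "removed_indels", "removed_multiallelic",
               "snps_retained", "unpolarized_excluded",
               "undefined_frequency_dropped", "records_scanned",
               "outliers", "impactful_outliers", "outliers_missing_annotation"),
    value = c(nrow(sites), filt$n_removed_indels, filt$n_removed_multiallelic,
              nrow(filt$snps), nrow(pol$excluded), nrow(rec$dropped),
              nrow(rec$records), nrow(scan$outliers), nrow(imp$kept),
              length(imp$missing))
  )
  stopifnot(scan_accounting(nrow(sites), filt$n_removed_indels,
                            filt$n_removed_multiallelic) == nrow(filt$snps),
            nrow(filt$snps) == nrow(pol$polarized) + nrow(pol$excluded),
            nrow(pol$polarized) == nrow(rec$records) + nrow(rec$dropped))

  hdr <- sprintf("dafscan scan report | mode=%s cutoff=%g pooling=%s fst=%s",
                 mode, cutoff, weighting, estimator)
  files <- list(
    accounting = file.path(out_dir, "accounting.tsv"),
    outliers = file.path(out_dir, "outliers.tsv"),
    impactful = file.path(out_dir, "impactful_outliers.tsv"),
    delta_hist = file.path(out_dir, "delta_daf_histogram.tsv"),
    daf_hist_a = file.path(out_dir, "daf_histogram_group_a.tsv"),
    daf_hist_b = file.path(out_dir, "daf_histogram_group_b.tsv"),
    excluded = file.path(out_dir, "excluded_variants.tsv")
  )
  .write_report_tsv(accounting, files$accounting, hdr)
  out_tab <- scan$outliers
  out_tab$daf_a <- round(out_tab$daf_a, 6)
  out_tab$daf_b <- round(out_tab$daf_b, 6)
  out_tab$delta_daf <- round(out_tab$delta_daf, 6)
  .write_report_tsv(out_tab, files$outliers, hdr)
  .write_report_tsv(imp$kept, files$impactful,
                    paste0(hdr, " | severity=", .severity_version))
  daf_edges <- seq(0, 1, by = daf_bin)
  .write_report_tsv(scan$histogram, files$delta_hist, hdr)
  .write_report_tsv(bin_distribution(rec$records$daf_a, daf_edges),
                    files$daf_hist_a, paste0(hdr, " | group=", grouping$a_label))
  .write_report_tsv(bin_distribution(rec$records$daf_b, daf_edges),
                    files$daf_hist_b, paste0(hdr, " | group=", grouping$b_label))
  .write_report_tsv(rbind(pol$excluded[, c("id", "reason")], rec$dropped),
                    files$excluded, hdr)

  invisible(list(sites = sites, snps = filt$snps, polarized = pol$polarized,
                 excluded = pol$excluded, records = rec$records,
                 dropped = rec$dropped, scan = scan, impactful = imp,
                 accounting = accounting, files = files))
}

#' Build and export a haplotype network around a focal SNP
#'
#' Selects the window around the focal SNP (LD r-squared rule, or a fixed
#' kb preset when `window_kb` is given), computes the pairwise LD table
#' and, when a two-group assignment of the haplotype populations is
#' supplied, per-site FST for the window SNPs, then builds the
#' median-joining network and exports it as GraphML, DOT and a node
#' table.
#'
#' @param haps A [haplotype_matrix()].
#' @param focal Focal site id or column index.
#' @param out_dir Output directory.
#' @param r2_max LD bound for window selection (default 0.2).
#' @param window_kb Optional fixed window size in kb centred on the focal
#'   SNP, overriding the r-squared rule.
#' @param epsilon Median-joining relaxation parameter.
#' @param fst_pops Optional list of two character vectors of population
#'   codes; per-site FST is computed between the pooled haplotype groups.
#' @param estimator FST estimator.
#' @return Invisible list: `window`, `ld`, `fst`, `network`, `files`.
#' @export
run_network <- function(haps, focal, out_dir, r2_max = 0.2,
                        window_kb = NULL, epsilon = 0L, fst_pops = NULL,
                        estimator = "weir_cockerham") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- if (is.numeric(focal)) focal else match(focal, haps$site_ids)
  if (is.na(f)) stop("focal site not found: ", focal)
  if (!is.null(window_kb)) {
    half <- window_kb * 1000 / 2
    centre <- haps$positions[f]
    idx <- which(haps$positions >= centre - half &
                   haps$positions <= centre + half)
    win <- list(start = min(idx), end = max(idx),
                site_ids = haps$site_ids[min(idx):max(idx)],
                span_bp = haps$positions[max(idx)] - haps$positions[min(idx)] + 1L,
                n_sites = max(idx) - min(idx) + 1L, r2 = NULL)
  } else {
    win <- select_window(haps, f, r2_max = r2_max)
  }
  sub <- haplotype_matrix(haps$mat[, win$start:win$end, drop = FALSE],
                          haps$site_ids[win$start:win$end],
                          haps$positions[win$start:win$end],
                          haps$pop_labels)
  ld <- ld_table(sub)

  fst <- NULL
  if (!is.null(fst_pops)) {
    ga <- haps$pop_labels %in% fst_pops[[1]]
    gb <- haps$pop_labels %in% fst_pops[[2]]
    dac_a <- colSums(sub$mat[ga, , drop = FALSE])
    dac_b <- colSums(sub$mat[gb, , drop = FALSE])
    vals <- site_fst(dac_a, rep(sum(ga), ncol(sub$mat)),
                     dac_b, rep(sum(gb), ncol(sub$mat)),
                     estimator = estimator)
    fst <- data.frame(id = sub$site_ids, fst = as.numeric(vals),
                      estimator = estimator,
                      negative = !is.na(vals) & vals < 0,
                      stringsAsFactors = FALSE)
  }

  net <- build_mj_network(collapse_haplotypes(sub), epsilon = epsilon)
  files <- list(
    graphml = file.path(out_dir, "network.graphml"),
    dot = file.path(out_dir, "network.dot"),
    nodes = file.path(out_dir, "network_nodes.tsv"),
    ld = file.path(out_dir, "ld_table.tsv"),
    window = file.path(out_dir, "window.tsv"),
    fst = file.path(out_dir, "site_fst.tsv")
  )
  export_network(net, files$graphml, "graphml")
  export_network(net, files$dot, "dot")
  write_node_table(net, files$nodes)
  hdr <- sprintf("dafscan network report | focal=%s r2_max=%g epsilon=%d",
                 haps$site_ids[f], r2_max, epsilon)
  .write_report_tsv(ld, files$ld, hdr)
  .write_report_tsv(
    data.frame(metric = c("window_start_id", "window_end_id",
                          "window_n_sites", "window_span_bp"),
               value = c(haps$site_ids[win$start], haps$site_ids[win$end],
                         win$n_sites, win$span_bp)),
    files$window, hdr)
  if (!is.null(fst)) .write_report_tsv(fst, files$fst, hdr)
  invisible(list(window = win, ld = ld, fst = fst, network = net,
                 files = files))
}
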