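# Balding-Nichols two-group synthetic datasets with known truth, written
# in the exact input dialects the pipeline consumes (VCF with AA and
# AC_/AN_ tags, BED, sample map, primate table, annotation table).

#' Configure a synthetic two-group SNP dataset
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: six populations (one African-like group-a population, five
#' group-b populations), 500 diploids each, 10,000 SNPs at divergence
#' F = 0.01, of which 100 are spiked to a true between-group difference
#' of 0.5.
#'
#' @param n_per_pop Diploid sample size per population.
#' @param pops_group_a,pops_group_b Population code vectors (disjoint).
#' @param n_sites Number of biallelic SNPs simulated (truth rows).
#' @param F_div Balding-Nichols divergence parameter in (0, 1) applied to
#'   every population.
#' @param spike_spec `data.frame` with columns `delta` (true between-group
#'   frequency difference in (0, 1]) and `count`.
#' @param aa_fraction Fraction of SNPs carrying an AA INFO tag; the
#'   primate table covers the rest.
#' @param n_indels,n_multiallelic Decoy non-SNP records interleaved into
#'   the emitted VCF to exercise the SNP filter (not part of the truth
#'   table).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 500L,
                       pops_group_a = "afr",
                       pops_group_b = c("amr", "asj", "eas", "fin", "nfe"),
                       n_sites = 10000L,
                       F_div = 0.01,
                       spike_spec = data.frame(delta = 0.5, count = 100L),
                       aa_fraction = 0.8,
                       n_indels = 200L,
                       n_multiallelic = 50L,
                       seed = 1L) {
  if (F_div <= 0 || F_div >= 1) stop("F_div must be in (0, 1)")
  if (nrow(spike_spec) && any(spike_spec$delta <= 0 | spike_spec$delta > 1)) {
    stop("spike deltas must be in (0, 1]")
  }
  if (sum(spike_spec$count) > n_sites) stop("more spikes than sites")
  if (length(intersect(pops_group_a, pops_group_b))) {
    stop("population groups must be disjoint")
  }
  structure(list(n_per_pop = as.integer(n_per_pop),
                 pops_group_a = pops_group_a, pops_group_b = pops_group_b,
                 n_sites = as.integer(n_sites), F_div = F_div,
                 spike_spec = spike_spec, aa_fraction = aa_fraction,
                 n_indels = as.integer(n_indels),
                 n_multiallelic = as.integer(n_multiallelic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rbn <- function(n, p, F_div) {
  # Balding-Nichols: Beta around p with Var = F * p * (1 - p)
  shape <- (1 - F_div) / F_div
  stats::rbeta(n, p * shape, (1 - p) * shape)
}

#' Simulate true per-population derived allele frequencies
#'
#' Each site draws an ancestral derived-allele frequency
#' `p ~ Uniform(0.05, 0.95)`; every population then drifts independently
#' under the Balding-Nichols model, `freq ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`,
#' whose variance is `F p (1-p)`. Spiked sites instead set the group mean
#' frequencies to `0.5 -/+ delta/2` and drift each population around its
#' group mean, so the true between-group difference is interpretable as
#' `delta`. The ancestral allele is assigned to ref or alt with equal
#' probability, so polarization is exercised in both orientations.
#'
#' @param config A [sim_config()].
#' @return `data.frame` of class `sim_truth` with one row per site:
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `ancestral`, `p_anc`, `spiked`,
#'   `spike_delta`, and `freq_<pop>` true derived frequencies.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  pops <- c(config$pops_group_a, config$pops_group_b)

  p_anc <- stats::runif(n, 0.05, 0.95)
  spiked <- logical(n)
  spike_delta <- rep(NA_real_, n)
  if (nrow(config$spike_spec)) {
    pool <- sample.int(n, sum(config$spike_spec$count))
    off <- 0L
    for (s in seq_len(nrow(config$spike_spec))) {
      idx <- pool[(off + 1L):(off + config$spike_spec$count[s])]
      spiked[idx] <- TRUE
      spike_delta[idx] <- config$spike_spec$delta[s]
      off <- off + config$spike_spec$count[s]
    }
  }

  freqs <- matrix(NA_real_, nrow = n, ncol = length(pops),
                  dimnames = list(NULL, pops))
  for (pop in pops) {
    centre <- p_anc
    if (any(spiked)) {
      in_a <- pop %in% config$pops_group_a
      centre[spiked] <- 0.5 + ifelse(in_a, -1, 1) * spike_delta[spiked] / 2
    }
    freqs[, pop] <- .rbn(n, centre, config$F_div)
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  anc_is_ref <- stats::runif(n) < 0.5

  out <- data.frame(
    chrom = "1",
    pos = seq(1000L, by = 25L, length.out = n),
    id = sprintf("site%05d", seq_len(n)),
    ref = ref, alt = alt,
    ancestral = ifelse(anc_is_ref, ref, alt),
    p_anc = p_anc, spiked = spiked, spike_delta = spike_delta,
    stringsAsFactors = FALSE
  )
  for (pop in pops) out[[paste0("freq_", pop)]] <- freqs[, pop]
  class(out) <- c("sim_truth", class(out))
  out
}

#' Emit a synthetic dataset in the pipeline's input formats
#'
#' Per-population derived allele counts are drawn
#' `Binomial(2 * n_per_pop, freq)` and written as gnomAD-style sites-only
#' `AC_<code>`/`AN_<code>` INFO fields (on the alt-allele scale, so counts
#' are flipped where the derived allele is ref). The configured fraction
#' of sites carries an `AA` tag; the primate table covers the remaining
#' sites with three concordant outgroup species. Decoy indel and
#' multiallelic records are interleaved to exercise the SNP filter. The
#' annotation table assigns each SNP one consequence term
#' (92% intron, 5% missense, 2% synonymous, 1% stop lost by default).
#'
#' @param truth A `sim_truth` from [simulate_frequencies()].
#' @param config The matching [sim_config()].
#' @param dir Output directory (created if needed).
#' @param consequence_props Named numeric vector of term proportions.
#' @return Named list of file paths: `vcf`, `bed`, `sample_map`,
#'   `primate`, `annotations`, `truth`.
#' @export
emit_dataset <- function(truth, config, dir,
                         consequence_props = c(intron_variant = 0.92,
                                               missense_variant = 0.05,
                                               synonymous_variant = 0.02,
                                               stop_lost = 0.01)) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  pops <- c(config$pops_group_a, config$pops_group_b)
  n <- nrow(truth)
  an <- 2L * config$n_per_pop

  sites <- truth[, c("chrom", "pos", "id", "ref", "alt")]
  aa_tag <- stats::runif(n) < config$aa_fraction
  sites$aa <- ifelse(aa_tag, truth$ancestral, NA_character_)
  derived_is_alt <- truth$ancestral == truth$ref
  for (pop in pops) {
    dac <- stats::rbinom(n, an, truth[[paste0("freq_", pop)]])
    sites[[paste0("ac_", pop)]] <- ifelse(derived_is_alt, dac, an - dac)
    sites[[paste0("an_", pop)]] <- an
  }

  # decoy non-SNP records interleaved between SNP positions
  n_decoy <- config$n_indels + config$n_multiallelic
  if (n_decoy > 0L) {
    decoy <- data.frame(
      chrom = "1",
      pos = sample(setdiff(seq(1001L, max(sites$pos)), sites$pos), n_decoy),
      id = sprintf("decoy%04d", seq_len(n_decoy)),
      ref = c(rep("AT", config$n_indels), rep("A", config$n_multiallelic)),
      alt = c(rep("A", config$n_indels), rep("C,G", config$n_multiallelic)),
      aa = NA_character_,
      stringsAsFactors = FALSE
    )
    for (pop in pops) {
      decoy[[paste0("ac_", pop)]] <- stats::rbinom(n_decoy, an, 0.1)
      decoy[[paste0("an_", pop)]] <- an
    }
    sites <- rbind(sites, decoy)
    sites <- sites[order(sites$pos), , drop = FALSE]
  }

  paths <- list(
    vcf = file.path(dir, "variants.vcf"),
    bed = file.path(dir, "regions.bed"),
    sample_map = file.path(dir, "sample_map.tsv"),
    primate = file.path(dir, "primate_alleles.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_variants(sites, paths$vcf,
                 header_extra = sprintf("##simulation_seed=%d", config$seed))
  writeLines(sprintf("1\t%d\t%d\tSIMGENE1", 0L, max(sites$pos) + 100L),
             paths$bed)

  samples <- unlist(lapply(pops, function(p) {
    sprintf("%s_s%04d", p, seq_len(config$n_per_pop))
  }))
  utils::write.table(
    data.frame(sample = samples, pop = rep(pops, each = config$n_per_pop)),
    paths$sample_map, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  no_aa <- which(!aa_tag)
  primate <- data.frame(
    chrom = rep(truth$chrom[no_aa], each = 3L),
    pos = rep(truth$pos[no_aa], each = 3L),
    species = rep(c("chimp", "gorilla", "orangutan"), length(no_aa)),
    allele = rep(truth$ancestral[no_aa], each = 3L),
    stringsAsFactors = FALSE
  )
  utils::write.table(primate, paths$primate, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  terms <- sample(names(consequence_props), n, replace = TRUE,
                  prob = consequence_props)
  utils::write.table(data.frame(id = truth$id, terms = terms),
                     paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Simulate phased haplotypes, optionally with an LD block
#'
#' Haplotype columns are independent Bernoulli draws from per-population
#' site frequencies except inside the optional block, where each
#' haplotype copies one of two template haplotypes (with a small per-site
#' mutation rate), creating strong within-block LD and low LD to outside
#' sites. Template choice probabilities differ by population, so block
#' sites are also differentiated. This is a deliberately simple stand-in
#' for recombination-driven LD, sufficient for exercising window
#' selection and network construction.
#'
#' @param n_hap_per_pop Haplotypes per population (must be even).
#' @param pops Population codes.
#' @param n_sites Number of sites.
#' @param block `NULL`, or integer vector of column indices forming the
#'   LD block.
#' @param template_prob Named (by population) probability of copying
#'   template 1 inside the block.
#' @param mutation_rate Per-site copy error rate inside the block.
#' @param maf_range Range of background (non-block) site frequencies.
#' @param seed Integer seed.
#' @return A [haplotype_matrix()].
#' @export
simulate_haplotypes <- function(n_hap_per_pop = 100L,
                                pops = c("YRI", "CHB", "CEU"),
                                n_sites = 20L,
                                block = NULL,
                                template_prob = NULL,
                                mutation_rate = 0.02,
                                maf_range = c(0.1, 0.5),
                                seed = 1L) {
  if (n_hap_per_pop %% 2L != 0L) stop("n_hap_per_pop must be even")
  set.seed(seed)
  n_hap <- n_hap_per_pop * length(pops)
  pop_labels <- rep(pops, each = n_hap_per_pop)
  freq <- stats::runif(n_sites, maf_range[1], maf_range[2])
  mat <- matrix(stats::rbinom(n_hap * n_sites, 1L, rep(freq, each = n_hap)),
                nrow = n_hap, ncol = n_sites)
  if (!is.null(block)) {
    if (is.null(template_prob)) {
      template_prob <- stats::setNames(
        seq(0.15, 0.85, length.out = length(pops)), pops)
    }
    t1 <- stats::rbinom(length(block), 1L, 0.5)
    t2 <- 1L - t1
    pick1 <- stats::runif(n_hap) < template_prob[pop_labels]
    for (h in seq_len(n_hap)) {
      tmpl <- if (pick1[h]) t1 else t2
      err <- stats::runif(length(block)) < mutation_rate
      mat[h, block] <- ifelse(err, 1L - tmpl, tmpl)
    }
  }
  haplotype_matrix(mat,
                   site_ids = sprintf("hsite%03d", seq_len(n_sites)),
                   positions = seq(500L, by = 40L, length.out = n_sites),
                   pop_labels = pop_labels)
}
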