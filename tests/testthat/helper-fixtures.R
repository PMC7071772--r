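# Small fixtures built in code at test time.

write_mini_vcf <- function(path, records,
                           info_ids = c("AA", "AC_afr", "AN_afr",
                                        "AC_nfe", "AN_nfe"),
                           samples = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    vapply(info_ids, function(id) {
      type <- if (id == "AA") "String" else "Integer"
      sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">', id, type, id)
    }, character(1)),
    if (!is.null(samples)) '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!is.null(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

mini_regions <- function(path = tempfile(fileext = ".bed"),
                         lines = "chr1\t100\t200\tGENE1") {
  writeLines(lines, path)
  path
}

afr_nfe_grouping <- function() {
  population_grouping("African", "afr", "non-African", "nfe")
}

six_pop_grouping <- function() {
  population_grouping("African", "afr", "non-African",
                      c("amr", "asj", "eas", "fin", "nfe"))
}

# Tiny simulated dataset used by several report tests.
tiny_sim <- function(seed = 11, n_sites = 300, spikes = 10, dir = tempfile()) {
  cfg <- sim_config(n_per_pop = 40L, n_sites = n_sites, seed = seed,
                    spike_spec = if (spikes > 0)
                      data.frame(delta = 0.5, count = spikes)
                    else data.frame(delta = numeric(), count = integer()),
                    n_indels = 8L, n_multiallelic = 4L)
  truth <- simulate_frequencies(cfg)
  paths <- emit_dataset(truth, cfg, dir)
  list(cfg = cfg, truth = truth, paths = paths)
}
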