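#!/usr/bin/env Rscript
# Stage 3: per-site FST for the scan outliers and LD structure on
# phased haplotypes.
#
# FST is computed with both estimators for every outlier SNP (African vs
# pooled non-African counts); the estimator is always recorded in the
# output. LD r2 is computed on a simulated three-population phased
# panel with a copy-with-mutation block, within each population group.

library(dafscan)

out <- read.delim("results/scan/outliers.tsv", comment.char = "#")
pol <- {
  data_dir <- "results/data"
  reg <- read_regions(file.path(data_dir, "regions.bed"))
  codes <- c("afr", "amr", "asj", "eas", "fin", "nfe")
  sites <- read_variants(file.path(data_dir, "variants.vcf"), reg, codes)
  filt <- filter_biallelic_snps(sites)
  calls <- assign_ancestral(
    filt$snps, read_primate_alleles(file.path(data_dir, "primate_alleles.tsv")))
  polarize(filt$snps, calls)$polarized
}
sel <- pol[match(out$id, pol$id), ]
nonafr <- c("amr", "asj", "eas", "fin", "nfe")
dac_b <- rowSums(sel[, paste0("dac_", nonafr)])
an_b <- rowSums(sel[, paste0("an_", nonafr)])
fst_tab <- data.frame(
  id = sel$id,
  delta_daf = out$delta_daf,
  fst_wc = as.numeric(site_fst(sel$dac_afr, sel$an_afr, dac_b, an_b,
                               "weir_cockerham")),
  fst_hudson = as.numeric(site_fst(sel$dac_afr, sel$an_afr, dac_b, an_b,
                                   "hudson"))
)
dir.create("results/popgen", showWarnings = FALSE, recursive = TRUE)
write.table(fst_tab, "results/popgen/outlier_fst.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("FST over %d outliers: Weir-Cockerham median %.3f, Hudson median %.3f\n",
            nrow(fst_tab), median(fst_tab$fst_wc, na.rm = TRUE),
            median(fst_tab$fst_hudson, na.rm = TRUE)))

haps <- simulate_haplotypes(n_hap_per_pop = 200, n_sites = 16,
                            block = 6:11, seed = 2L)
ld_afr <- ld_table(haps, pops = "YRI")
ld_non <- ld_table(haps, pops = c("CHB", "CEU"))
ld <- rbind(ld_afr, ld_non)
write.table(ld, "results/popgen/ld_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
in_block <- with(ld_afr, id_i %in% sprintf("hsite%03d", 6:11) &
                   id_j %in% sprintf("hsite%03d", 6:11))
cat(sprintf("YRI mean r2 within the LD block: %.3f; outside: %.3f\n",
            mean(ld_afr$r2[in_block], na.rm = TRUE),
            mean(ld_afr$r2[!in_block], na.rm = TRUE)))
cat("LD long table: results/popgen/ld_table.tsv\n")
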