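#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-group study dataset.
#
# Six populations (afr vs amr/asj/eas/fin/nfe), 500 diploids each,
# 10,000 SNPs drifted under Balding-Nichols F = 0.01 from uniform
# ancestral frequencies; 100 loci spiked to a true between-group
# difference of 0.5; 200 indel and 50 multiallelic decoy records test
# the SNP filter. All downstream stages read these files.

library(dafscan)

out_dir <- "results/data"
cfg <- sim_config(seed = 1L)
truth <- simulate_frequencies(cfg)
paths <- emit_dataset(truth, cfg, out_dir)

cat("Simulated", nrow(truth), "SNPs (", sum(truth$spiked), "spiked at delta",
    unique(na.omit(truth$spike_delta)), ") +", cfg$n_indels, "indel and",
    cfg$n_multiallelic, "multiallelic decoys\n")
cat("Wrote:", paste(unlist(paths), collapse = "\n       "), "\n")
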