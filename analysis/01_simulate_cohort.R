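#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic myeloma cohort.
#
# Generates a 634-sample cohort with the default class structure (~3.6%
# biallelic, ~9.8% monoallelic, 42% of the monoallelic samples cryptically
# biallelic with a planted transcriptomic mechanism) plus 5 normal
# plasma-cell controls, and writes the bundle as plain TSV/JSON under
# results/cohort/.

suppressPackageStartupMessages(library(tp53screen))

seed <- 101L
cfg <- cohort_config(n_samples = 634, seed = seed)
bundle <- generate_cohort(cfg)
print(bundle)

dir <- "results/cohort"
write_bundle(bundle, dir)
cat("wrote cohort bundle to", dir, "\n")
print(table(bundle$truth$true_status, bundle$truth$planted_mechanism))
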