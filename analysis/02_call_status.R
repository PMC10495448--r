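#!/usr/bin/env Rscript
# Stage 2: DNA-level TP53 status calling.
#
# Reads the cohort's mutation/CNV/BAF tables and applies the rule-based
# classifier: biallelic = deep deletion, mutation+deletion or mutation+LOH;
# a single hit is monoallelic.  Verifies the calls against the generator's
# DNA-level ground truth and writes results/status_calls.tsv.

suppressPackageStartupMessages(library(tp53screen))

bundle <- read_bundle("results/cohort")
calls <- call_tp53_status(bundle$samples, bundle$mutations,
                          bundle$segments, bundle$baf)
print(table(calls$status, calls$evidence_rule))

dna_truth <- ifelse(bundle$truth$true_status == "cryptic_biallelic",
                    "monoallelic", bundle$truth$true_status)
cat(sprintf("agreement with DNA-level ground truth: %.1f%%\n",
            100 * mean(calls$status == dna_truth)))

dir.create("results", showWarnings = FALSE)
write.table(calls, "results/status_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
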