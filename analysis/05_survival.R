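#!/usr/bin/env Rscript
# Stage 5: survival stratification by the refined TP53 grouping.
#
# Derives PFS/OS from the clinical table, estimates Kaplan-Meier curves for
# known biallelic / predicted biallelic / predicted monoallelic / WT, and
# tests the combined (known + predicted) biallelic group against the
# others with the log-rank test.

suppressPackageStartupMessages(library(tp53screen))

bundle <- read_bundle("results/cohort")
calls <- read.delim("results/status_calls.tsv")
pred <- read.delim("results/pipeline/predictions.tsv")
pred_biall <- pred$sample_id[pred$source_set == "discovery" &
                               pred$predicted_label == "predicted_biallelic"]

grp <- setNames(rep("WT", length(bundle$samples)), bundle$samples)
grp[calls$sample_id[calls$status == "monoallelic"]] <- "predicted_monoallelic"
grp[pred_biall] <- "predicted_biallelic"
grp[calls$sample_id[calls$status == "biallelic"]] <- "known_biallelic"

clin <- bundle$clinical
clin$group <- grp[clin$sample_id]
records <- derive_endpoints(clin)

for (ep in c("PFS", "OS")) {
  rec <- records[records$endpoint == ep, ]
  cat("\n==", ep, "==\n")
  for (g in unique(rec$group)) {
    km <- km_estimate(rec$time[rec$group == g], rec$event[rec$group == g])
    cat(sprintf("  %-22s n=%3d  median %s days\n", g, km$n,
                km$median_label))
  }
  comb <- rec[rec$group %in% c("known_biallelic", "predicted_biallelic"), ]
  for (ref in c("predicted_monoallelic", "WT")) {
    other <- rec[rec$group == ref, ]
    lr <- logrank_test(comb$time, comb$event, other$time, other$event)
    cat(sprintf("  combined biallelic vs %-22s log-rank p = %.4g\n",
                ref, lr$p))
  }
}

surv_json <- lapply(c("PFS", "OS"), function(ep) {
  rec <- records[records$endpoint == ep, ]
  meds <- lapply(split(rec, rec$group), function(r) {
    km <- km_estimate(r$time, r$event)
    if (is.na(km$median)) "not reached" else km$median
  })
  comb <- rec[rec$group %in% c("known_biallelic", "predicted_biallelic"), ]
  wt <- rec[rec$group == "WT", ]
  lr <- logrank_test(comb$time, comb$event, wt$time, wt$event)
  list(endpoint = ep, medians = meds,
       logrank_combined_vs_wt = list(statistic = lr$statistic, p = lr$p))
})
jsonlite::write_json(surv_json, "results/survival.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nwrote results/survival.json\n")
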