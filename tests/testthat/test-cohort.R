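small_config <- function(...) {
  cohort_config(n_samples = 120, n_background_genes = 40, ...)
}

test_that("a fixed seed gives identical bundles", {
  b1 <- generate_cohort(small_config(seed = 7))
  b2 <- generate_cohort(small_config(seed = 7))
  expect_identical(b1[setdiff(names(b1), "config")],
                   b2[setdiff(names(b2), "config")])
  b3 <- generate_cohort(small_config(seed = 8))
  expect_false(identical(b1$expression, b3$expression))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_samples = 5), ">= 10")
  expect_error(cohort_config(prevalence_biallelic = 0.7,
                             prevalence_monoallelic = 0.5), "sum")
  expect_error(cohort_config(censor_rate = 1.2), "fractions")
  expect_error(cohort_config(splicing_planted_psi = -0.1), "fractions")
  expect_error(cohort_config(mean_depth = 0), "positive")
})

test_that("biallelic counts follow the configured prevalence", {
  counts <- vapply(1:200, function(s) {
    b <- generate_cohort(cohort_config(n_samples = 1000,
                                       n_background_genes = 5,
                                       n_normals = 2, seed = s))
    sum(b$truth$true_status == "biallelic")
  }, numeric(1))
  se_mean <- sqrt(1000 * 0.036 * 0.964 / 200)
  expect_lt(abs(mean(counts) - 36), 3 * se_mean)
})

test_that("DNA tables reproduce the DNA-level truth for every sample", {
  for (s in c(3, 11)) {
    b <- generate_cohort(small_config(seed = s))
    calls <- call_tp53_status(b$samples, b$mutations, b$segments, b$baf)
    dna_truth <- ifelse(b$truth$true_status == "cryptic_biallelic",
                        "monoallelic", b$truth$true_status)
    expect_equal(calls$status, dna_truth)
    # evidence rules match the generator's DNA rule where one was planted
    planted <- b$truth$dna_rule != "none"
    expect_equal(calls$evidence_rule[planted], b$truth$dna_rule[planted])
  }
})

test_that("cryptic biallelic samples carry exactly one DNA hit", {
  b <- generate_cohort(cohort_config(n_samples = 400,
                                     n_background_genes = 20, seed = 5))
  calls <- call_tp53_status(b$samples, b$mutations, b$segments, b$baf)
  cryptic <- b$truth$true_status == "cryptic_biallelic"
  expect_true(all(calls$status[cryptic] == "monoallelic"))
  expect_true(all(b$truth$planted_mechanism[cryptic] != "none"))
})

test_that("splicing counts are an unbiased PSI draw", {
  set.seed(13)
  expect_true(all(simulate_splicing_counts(rep(0, 100), 50)$intron_reads == 0))
  expect_true(all(simulate_splicing_counts(rep(1, 100), 50)$junction_reads == 0))
  cts <- simulate_splicing_counts(rep(0.3, 1e4), 200)
  psi <- compute_psi(cts$intron_reads, cts$junction_reads)
  expect_lt(abs(mean(psi, na.rm = TRUE) - 0.3), 0.01)
  expect_error(simulate_splicing_counts(0.5, -1), "positive")
  expect_error(simulate_splicing_counts(1.5, 10), "psi_target")
})

test_that("planted PSI is recoverable with small bias at depth 200", {
  b <- generate_cohort(cohort_config(n_samples = 1500,
                                     n_background_genes = 10, seed = 21))
  sp <- b$splicing
  sp$psi <- compute_psi(sp$intron_reads, sp$junction_reads)
  planted <- b$truth$sample_id[b$truth$planted_mechanism %in%
                                 c("cryptic_exon+LOH", "cryptic_exon+deletion")]
  got <- sp$psi[sp$sample_id %in% planted &
                  sp$event_class == "cryptic_exon"]
  expect_gt(length(got), 10)
  expect_lt(abs(mean(got) - b$config$splicing_planted_psi), 0.02)
})

test_that("survival simulation has the configured scale and censoring", {
  set.seed(3)
  d <- simulate_survival_times(1e4, 693)
  expect_equal(d$event, rep(1, 1e4))          # censor_rate 0
  expect_lt(abs(mean(d$time) - 693 / log(2)) / 1000, 0.03)
  dc <- simulate_survival_times(2000, 693, censor_rate = 0.5)
  expect_gt(mean(dc$event == 0), 0.05)
  expect_error(simulate_survival_times(10, -5), "positive")
})

test_that("a zero-effect signature yields a chance-level classifier", {
  b <- generate_cohort(cohort_config(n_samples = 300,
                                     n_background_genes = 30,
                                     prevalence_biallelic = 0.1,
                                     signature_log2_effect = 0, seed = 9))
  affected <- b$truth$true_status %in% c("biallelic", "cryptic_biallelic")
  sig <- grep("^SIG", rownames(b$expression), value = TRUE)
  x <- t(log_transform(b$expression[sig, ]))
  params <- list(n_trees = 10, min_samples_leaf_fraction = 0.1,
                 min_weight_fraction_leaf = 0.05)
  fit <- fit_forest(x, as.integer(affected), params, seed = 2)
  # in-bag scores on a held-out-free fit still carry no signal out of bag;
  # use a split to avoid memorisation
  tr <- seq_len(200)
  fit <- fit_forest(x[tr, ], as.integer(affected[tr]), params, seed = 2)
  ev <- evaluate_scores(predict(fit, x[-tr, ]), as.integer(affected[-tr]))
  expect_gt(ev$auroc, 0.25)
  expect_lt(ev$auroc, 0.75)
})

test_that("the planted regulator ranks first among all genes", {
  hits <- vapply(1:5, function(s) {
    b <- generate_cohort(cohort_config(n_samples = 200,
                                       n_background_genes = 30, seed = s))
    sp <- b$splicing[b$splicing$event_class == "cryptic_exon", ]
    sp$psi <- compute_psi(sp$intron_reads, sp$junction_reads)
    normals <- sp$sample_id %in% b$normal_ids
    base <- mean(sp$psi[normals], na.rm = TRUE)
    dpsi <- setNames(base - sp$psi[!normals], sp$sample_id[!normals])
    res <- rank_splicing_regulators(log_transform(b$expression), dpsi)
    res$gene[1] == "MED18"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
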