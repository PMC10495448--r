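test_that("PSI follows the count formula and flags degenerate input", {
  expect_equal(compute_psi(10, 30), 0.25)
  expect_equal(compute_psi(0, 50), 0)
  expect_equal(compute_psi(40, 0), 1)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5), "non-negative")
  # strictly increasing in intron reads at fixed junction reads
  psi <- compute_psi(0:50, 20)
  expect_true(all(diff(psi) > 0))
})

test_that("dPSI is normal minus tumor and antisymmetric", {
  d <- compute_dpsi(c(0.05, 0.05, 0.05), 0.59)
  expect_equal(d$dpsi, -0.54)
  expect_equal(compute_dpsi(c(0.2, 0.4), c(0.4, 0.2))$dpsi, 0)
  set.seed(31)
  for (i in 1:50) {
    a <- runif(5); b <- runif(3)
    expect_equal(compute_dpsi(a, b)$dpsi, -compute_dpsi(b, a)$dpsi)
    expect_lte(abs(compute_dpsi(a, b)$dpsi), 1)
  }
  expect_error(compute_dpsi(c(NA, NA), 0.5), "undefined")
})

test_that("transcript classification follows the cryptic-exon class map", {
  cmap <- default_class_map()
  expect_equal(classify_transcript("TP53_TA_alpha", cmap), "TA_alpha")
  expect_equal(classify_transcript("TP53_TA_beta", cmap), "TA_beta")
  expect_equal(classify_transcript("TP53_d133_gamma", cmap), "d133_gamma")
  expect_true(is.na(classify_transcript("ENST_UNKNOWN", cmap)))
  expect_equal(nrow(cmap), 12)
  expect_setequal(classify_transcript(cmap$transcript_id, cmap),
                  isoform_classes())
})

test_that("isoform imbalance ratio handles the documented cases", {
  expect_equal(isoform_imbalance_ratio(
    c(TA_alpha = 1.0, TA_beta = 1.0, TA_gamma = 0.95)), 1.95)
  expect_equal(isoform_imbalance_ratio(
    c(TA_alpha = 2, TA_beta = 0, TA_gamma = 0)), 0)
  expect_true(is.infinite(isoform_imbalance_ratio(
    c(TA_alpha = 0, TA_beta = 1, TA_gamma = 0))))
  expect_true(is.na(isoform_imbalance_ratio(
    c(TA_alpha = 0, TA_beta = 0, TA_gamma = 0))))
})

test_that("regulator ranking finds a monotone-linked gene first", {
  set.seed(17)
  n <- 40
  dpsi <- setNames(runif(n, -0.6, 0), sprintf("s%02d", 1:n))
  expr <- matrix(rnorm(20 * n, 3, 1), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), names(dpsi)))
  expr["g01", ] <- rank(-dpsi)  # strictly decreasing in dpsi
  res <- rank_splicing_regulators(expr, dpsi)
  expect_equal(res$gene[1], "g01")
  expect_equal(res$rho[1], -1)
  # tie-free Spearman equals Pearson on ranks
  g5 <- expr["g05", ]
  expect_equal(res$rho[res$gene == "g05"],
               cor(rank(g5), rank(dpsi)), tolerance = 1e-12)
  expect_error(rank_splicing_regulators(expr, dpsi * 0), "constant")
  expect_error(rank_splicing_regulators(expr[, 1:3], dpsi[1:3]), ">= 5")
})

test_that("null genes show small correlations against permuted dPSI", {
  set.seed(23)
  n <- 100
  dpsi <- setNames(runif(n, -0.6, 0), sprintf("s%03d", 1:n))
  g <- rnorm(n)
  rhos <- replicate(1000, cor(g, sample(dpsi), method = "spearman"))
  expect_lt(abs(mean(rhos)), 0.02)
  expect_lt(quantile(abs(rhos), 0.95), 0.25)
})

test_that("VAF-splicing association recovers a planted link", {
  mono <- vaf_splicing_association(c(0.83, 0.72, 0.26), c(0.6, 0.5, 0.2))
  expect_equal(mono$rho, 1)
  const <- vaf_splicing_association(c(0.83, 0.72, 0.26), c(0.3, 0.3, 0.3))
  expect_equal(const$rho, 0)
  expect_equal(const$p, 1)
  set.seed(41)
  vaf <- runif(30, 0.05, 0.9)
  psi <- pmin(1, pmax(0, vaf * 0.8 + rnorm(30, 0, 0.05)))
  link <- vaf_splicing_association(vaf, psi)
  expect_gt(link$rho, 0.7)
  # low-VAF non-splicing samples are flagged
  expect_true(all(link$table$low_vaf_no_splicing ==
                    (vaf < 0.2 & psi < 0.2)))
  expect_error(vaf_splicing_association(c(0.5, 0.6), c(0.1, 0.2)), ">= 3")
})

test_that("mechanism rules reproduce the worked per-sample calls", {
  # copy-neutral LOH with strong cryptic-exon inclusion
  m1 <- assign_mechanism("S1", dpsi_cryptic = -0.54,
                         ri_events = data.frame(psi = numeric(0),
                                                normal_psi = numeric(0)),
                         gene_log_expr = 3, gene_log2fc_vs_normal = 0)
  expect_equal(m1$labels, "cryptic_exon_inclusion")
  # deletion with low residual expression
  m2 <- assign_mechanism("S2", dpsi_cryptic = 0.01,
                         ri_events = data.frame(psi = numeric(0),
                                                normal_psi = numeric(0)),
                         gene_log_expr = 1.01,
                         gene_log2fc_vs_normal = -0.89)
  expect_equal(m2$labels, "low_total_expression")
  # high-VAF splice-site mutation with a novel retained intron
  m3 <- assign_mechanism("S3", dpsi_cryptic = 0,
                         ri_events = data.frame(psi = 0.45,
                                                normal_psi = 0.01),
                         gene_log_expr = 3, gene_log2fc_vs_normal = 0,
                         splice_mutation_vafs = 0.83)
  expect_setequal(m3$labels, c("retained_intron",
                               "splice_site_mutation_driven"))
  # splice-site mutation without splicing evidence stays unexplained
  m4 <- assign_mechanism("S4", dpsi_cryptic = 0,
                         ri_events = data.frame(psi = 0.01,
                                                normal_psi = 0.01),
                         gene_log_expr = 3, gene_log2fc_vs_normal = 0,
                         splice_mutation_vafs = 0.83)
  expect_equal(m4$labels, "unexplained")
  # missing layers are reported
  m5 <- assign_mechanism("S5")
  expect_equal(m5$labels, "unexplained")
  expect_setequal(m5$missing_layers,
                  c("cryptic_exon_dpsi", "retained_introns",
                    "gene_expression"))
})
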