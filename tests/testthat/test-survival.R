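test_that("endpoint derivation follows the PFS/OS/ARS definitions", {
  clin <- data.frame(
    sample_id = c("A", "B", "C"),
    diagnosis_date = c(0, 0, 0),
    progression_date = c(NA, NA, 300),
    death_date = c(400, NA, 800),
    last_followup_date = c(400, 900, 800),
    first_abnormality_date = c(NA, NA, 300),
    stringsAsFactors = FALSE)
  rec <- derive_endpoints(clin)
  a_pfs <- rec[rec$sample_id == "A" & rec$endpoint == "PFS", ]
  expect_equal(a_pfs$time, 400); expect_equal(a_pfs$event, 1)
  b_os <- rec[rec$sample_id == "B" & rec$endpoint == "OS", ]
  expect_equal(b_os$time, 900); expect_equal(b_os$event, 0)
  c_ars <- rec[rec$sample_id == "C" & rec$endpoint == "ARS", ]
  expect_equal(c_ars$time, 500); expect_equal(c_ars$event, 1)
  # only the sample with an abnormality date contributes an ARS record
  expect_equal(sum(rec$endpoint == "ARS"), 1)
  # Date columns behave like day offsets
  clin2 <- clin
  for (col in grep("_date$", names(clin2)))
    clin2[[col]] <- as.Date("2015-01-01") + clin2[[col]]
  expect_equal(derive_endpoints(clin2)$time, rec$time)
  clin$death_date[1] <- -5
  expect_error(derive_endpoints(clin), "non-positive")
})

test_that("Kaplan-Meier without censoring equals empirical survival", {
  km <- km_estimate(1:10, rep(1, 10))
  expect_equal(km$steps$surv, 1 - (1:10) / 10)
  expect_equal(km$median, 5)
  expect_equal(km_surv(km, c(0.5, 5, 20)), c(1, 0.5, 0))
  # all censored: flat at 1, median not reached
  flat <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_equal(nrow(flat$steps), 0)
  expect_true(is.na(flat$median))
  expect_equal(flat$median_label, "not reached")
  single <- km_estimate(3, 1)
  expect_equal(single$steps$surv, 0)
  expect_equal(single$median, 3)
  expect_error(km_estimate(numeric(0), numeric(0)), "length")
})

test_that("Kaplan-Meier matches survival::survfit with censoring", {
  skip_if_not_installed("survival")
  set.seed(19)
  time <- round(rexp(60, 1 / 100)) + 1
  event <- rbinom(60, 1, 0.7)
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  sf_at_events <- summary(sf, times = km$steps$time)
  expect_equal(km$steps$surv, sf_at_events$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand-computed 4-subject case", {
  lr <- logrank_test(c(2, 4), c(1, 1), c(6, 8), c(1, 1))
  # hypergeometric terms: O = 2, E = 1/2 + 1/3, V = 1/4 + 2/9
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6)
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
  ident <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("log-rank is group-symmetric and matches survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(29)
  for (i in 1:10) {
    ta <- round(rexp(25, 1 / 300)) + 1; ea <- rbinom(25, 1, 0.8)
    tb <- round(rexp(25, 1 / 500)) + 1; eb <- rbinom(25, 1, 0.8)
    lr <- logrank_test(ta, ea, tb, eb)
    lr_swap <- logrank_test(tb, eb, ta, ea)
    expect_equal(lr$statistic, lr_swap$statistic, tolerance = 1e-12)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, each = 25))
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("a strong planted hazard difference is detected", {
  set.seed(37)
  pvals <- replicate(40, {
    a <- simulate_survival_times(200, 478)
    b <- simulate_survival_times(200, 1176)
    logrank_test(a$time, a$event, b$time, b$event)$p
  })
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("Mann-Whitney U matches enumeration and identities", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  expect_equal(mw$method, "exact enumeration")
  # U(x, y) + U(y, x) = nx * ny
  set.seed(43)
  for (i in 1:20) {
    x <- sample(1:20, 4, replace = TRUE)
    y <- sample(1:20, 5, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 20)
  }
  ident <- mann_whitney_u(c(2, 5, 5), c(2, 5, 5))
  expect_equal(ident$p, 1)
  # tie-free exact p agrees with wilcox.test's exact distribution
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 4)
    x2 <- sample(seq(0.1, 99, by = 0.7), 5)
    y2 <- sample(seq(0.3, 99, by = 1.1), 6)
    wt <- suppressWarnings(wilcox.test(x2, y2, exact = TRUE))
    expect_equal(mann_whitney_u(x2, y2)$p, wt$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("large-sample Mann-Whitney approximation tracks wilcox.test", {
  set.seed(47)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mw <- mann_whitney_u(x, y)
  expect_equal(mw$method, "normal approximation")
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
})
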