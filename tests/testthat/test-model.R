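test_that("stratified split preserves class proportions and partitions", {
  samples <- sprintf("S%03d", 1:572)
  labels <- rep(c(1L, 0L), c(23, 549))
  sp <- stratified_split(samples, labels, ratio = 0.7, seed = 3)
  pos_train <- sum(samples[labels == 1] %in% sp$training)
  expect_equal(pos_train, 16)
  expect_equal(23 - pos_train, 7)
  expect_equal(sum(samples[labels == 0] %in% sp$training), 384)
  expect_setequal(c(sp$training, sp$validation), samples)
  expect_length(intersect(sp$training, sp$validation), 0)
  sp2 <- stratified_split(samples, labels, ratio = 0.7, seed = 3)
  expect_identical(sp, sp2)
  expect_error(stratified_split(c("a", "b"), c(1, 0)), ">= 2")
})

test_that("hyperparameter grid has the documented shape", {
  g <- hyperparameter_grid(16)
  expect_equal(sort(unique(g$n_trees)), 2:15)          # open (1, 16)
  expect_length(unique(g$min_samples_leaf_fraction), 19)
  expect_length(unique(g$min_weight_fraction_leaf), 19)
  expect_equal(nrow(g), 14 * 19 * 19)
  expect_error(hyperparameter_grid(2), "empty tree range")
})

test_that("forest separates a separable toy and scores within [0, 1]", {
  toy <- toy_features(n_pos = 10, n_neg = 40, n_genes = 1, shift = 5,
                      sd = 0.3, seed = 2)
  params <- list(n_trees = 10, min_samples_leaf_fraction = 0.05,
                 min_weight_fraction_leaf = 0.05)
  fit <- fit_forest(toy$x, toy$y, params, seed = 1)
  scores <- predict(fit, toy$x)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(evaluate_scores(scores, toy$y)$auroc, 1)
  expect_error(fit_forest(toy$x, rep(0, nrow(toy$x)), params),
               "both classes")
})

test_that("forest fitting is deterministic given the seed", {
  toy <- toy_features(seed = 4)
  params <- list(n_trees = 5, min_samples_leaf_fraction = 0.1,
                 min_weight_fraction_leaf = 0.05)
  s1 <- predict(fit_forest(toy$x, toy$y, params, seed = 9), toy$x)
  s2 <- predict(fit_forest(toy$x, toy$y, params, seed = 9), toy$x)
  expect_identical(s1, s2)
})

test_that("permuted labels give chance-level AUROC", {
  toy <- toy_features(n_pos = 20, n_neg = 40, seed = 6)
  params <- list(n_trees = 8, min_samples_leaf_fraction = 0.1,
                 min_weight_fraction_leaf = 0.05)
  set.seed(11)
  aurocs <- replicate(50, {
    y_perm <- sample(toy$y)
    fit <- fit_forest(toy$x, y_perm, params,
                      seed = sample.int(1e6, 1))
    evaluate_scores(predict(fit, toy$x[sample(nrow(toy$x)), ]),
                    sample(toy$y))$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("a saturating leaf fraction collapses scores to the label mean", {
  toy <- toy_features(n_pos = 10, n_neg = 40, shift = 5, seed = 8)
  params <- list(n_trees = 10, min_samples_leaf_fraction = 0.95,
                 min_weight_fraction_leaf = 0.95)
  fit <- fit_forest(toy$x, toy$y, params, seed = 1)
  scores <- predict(fit, toy$x)
  expect_lt(max(abs(scores - mean(toy$y))), 0.15)
})

test_that("model selection is AUPRC-first with an AUROC floor", {
  row <- function(auprc, auroc, trees = 10, f = 0.05)
    data.frame(n_trees = trees, min_samples_leaf_fraction = f,
               min_weight_fraction_leaf = f, auroc = auroc, auprc = auprc)
  # highest AUPRC wins when both clear the floor
  g <- rbind(row(0.6, 0.9), row(0.7, 0.9))
  expect_equal(select_best_model(g)$auprc, 0.7)
  # AUROC floor beats raw AUPRC
  g <- rbind(row(0.9, 0.7), row(0.6, 0.85))
  expect_equal(select_best_model(g)$auprc, 0.6)
  # tie-break: fewer trees
  g <- rbind(row(0.7, 0.9, trees = 25), row(0.7, 0.9, trees = 5))
  expect_equal(select_best_model(g)$n_trees, 5)
  # tie-break: larger leaf fraction at equal trees
  g <- rbind(row(0.7, 0.9, f = 0.05), row(0.7, 0.9, f = 0.5))
  expect_equal(select_best_model(g)$min_samples_leaf_fraction, 0.5)
  # fallback with warning when nothing clears the floor
  g <- rbind(row(0.5, 0.6), row(0.4, 0.7))
  expect_warning(best <- select_best_model(g), "AUROC floor")
  expect_false(best$auroc_floor_met)
  expect_equal(best$auprc, 0.5)
  expect_error(select_best_model(g[0, ]), "empty grid")
})

test_that("grid search deduplication reproduces per-member fits", {
  toy <- toy_features(n_pos = 12, n_neg = 48, seed = 10)
  set.seed(10)
  tr <- sort(c(sample(1:12, 8), sample(13:60, 32)))
  va <- setdiff(1:60, tr)
  grid <- expand.grid(n_trees = c(3, 6),
                      min_samples_leaf_fraction = c(0.05, 0.3),
                      min_weight_fraction_leaf = c(0.05, 0.3))
  gr <- grid_search(toy$x[tr, ], toy$y[tr], toy$x[va, ], toy$y[va],
                    grid, seed = 5)
  for (i in seq_len(nrow(gr))) {
    fit <- fit_forest(toy$x[tr, ], toy$y[tr], gr[i, ], seed = 5)
    ev <- evaluate_scores(predict(fit, toy$x[va, ]), toy$y[va])
    expect_equal(gr$auroc[i], ev$auroc)
    expect_equal(gr$auprc[i], ev$auprc)
  }
})

test_that("cross-validation partitions samples and finds strong signal", {
  toy <- toy_features(n_pos = 15, n_neg = 60, shift = 3, seed = 12)
  params <- list(n_trees = 10, min_samples_leaf_fraction = 0.05,
                 min_weight_fraction_leaf = 0.05)
  folds <- cross_validate(toy$x, toy$y, params, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_true(all(folds > 0.8))
  expect_error(cross_validate(toy$x[1:10, ], c(1, 1, rep(0, 8)), params,
                              k = 5), "fewer positives")
})

test_that("the maximum-sensitivity cutoff always reaches 100% sensitivity", {
  scores <- c(0.7, 0.4, 0.9, 0.3, 0.1)
  labels <- c(1, 1, 0, 0, 0)
  cut <- select_cutoff(scores, labels)
  expect_equal(cut, 0.4)
  expect_equal(mean(scores[labels == 1] >= cut), 1)     # sensitivity
  expect_equal(mean(scores[labels == 0] < cut), 2 / 3)  # specificity
  # separable case: specificity 1
  expect_equal(mean(c(0.3, 0.2, 0.1) < select_cutoff(c(0.9, 0.8, 0.3, 0.2, 0.1),
                                                     c(1, 1, 0, 0, 0))), 1)
  expect_error(select_cutoff(runif(3), c(0, 0, 0)), "no positives")
})

test_that("prediction uses an inclusive cutoff and validates features", {
  toy <- toy_features(n_pos = 10, n_neg = 40, shift = 4, seed = 14)
  params <- list(n_trees = 8, min_samples_leaf_fraction = 0.05,
                 min_weight_fraction_leaf = 0.05)
  forest <- fit_forest(toy$x, toy$y, params, seed = 3)
  scores <- predict(forest, toy$x)
  model <- list(forest = forest, cutoff = sort(unique(scores))[2])
  pred <- predict_biallelic(model, toy$x)
  at_cut <- pred$score == model$cutoff
  expect_true(all(pred$predicted_label[at_cut] == "predicted_biallelic"))
  expect_error(predict_biallelic(model, toy$x[, -1, drop = FALSE]),
               "missing genes")
  empty <- predict_biallelic(model, toy$x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  # tightening the cutoff never increases the predicted-positive count
  counts <- vapply(sort(unique(scores)), function(cut)
    sum(scores >= cut), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
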