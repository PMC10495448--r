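# The regression-forest biallelic scorer: stratified splitting, the
# hyperparameter grid, forest fitting, AUPRC-first model selection,
# cross-validation, the maximum-sensitivity cutoff, and discovery-set
# prediction.

#' Stratified 7:3 train/validation split
#'
#' Samples are split within each class so class proportions are preserved up
#' to rounding; the two sets are disjoint and exhaustive.
#'
#' @param samples Character vector of sample IDs.
#' @param labels Binary vector (0/1) aligned with \code{samples}; both
#'   classes must have >= 2 members.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with character vectors \code{training} and
#'   \code{validation}.
#' @export
stratified_split <- function(samples, labels, ratio = 0.7, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(samples) == length(labels), all(labels %in% 0:1))
  if (min(table(labels)) < 2) stop("each class needs >= 2 members")
  set.seed(seed)
  train <- character(0)
  for (cls in c(1L, 0L)) {
    ids <- samples[labels == cls]
    n_train <- round(ratio * length(ids))
    n_train <- max(1L, min(length(ids) - 1L, n_train))
    train <- c(train, sample(ids, n_train))
  }
  list(training = train, validation = setdiff(samples, train))
}

#' Hyperparameter grid for the regression forest
#'
#' Tree counts run over the open integer interval (1, n_genes), i.e.
#' 2 .. n_genes - 1; the two leaf-fraction parameters each run over
#' (0, 1) with an offset of 0.05, i.e. 0.05, 0.10, ..., 0.95.  The grid is
#' the full Cartesian product.
#'
#' @param n_genes Number of candidate genes (>= 3 for a non-empty tree
#'   range).
#' @return data.frame with columns \code{n_trees},
#'   \code{min_samples_leaf_fraction}, \code{min_weight_fraction_leaf}.
#' @export
hyperparameter_grid <- function(n_genes) {
  if (n_genes < 3) stop("n_genes < 3 gives an empty tree range")
  fractions <- seq(0.05, 0.95, by = 0.05)
  expand.grid(n_trees = 2:(n_genes - 1),
              min_samples_leaf_fraction = fractions,
              min_weight_fraction_leaf = fractions,
              KEEP.OUT.ATTRS = FALSE)
}

# With unweighted samples the two leaf-fraction parameters impose the same
# constraint; the binding one is the larger, converted to a node size.
effective_nodesize <- function(params, n_train) {
  f <- max(params$min_samples_leaf_fraction, params$min_weight_fraction_leaf)
  max(1L, as.integer(ceiling(f * n_train)))
}

#' Fit a regression forest scorer on 0/1 labels
#'
#' An ensemble of bootstrap-sampled regression trees whose averaged
#' prediction lies in [0, 1] when labels are 0/1; the score is the ensemble
#' mean.  Leaf-size regularisation is applied through the minimum terminal
#' node size implied by the leaf-fraction parameters.
#'
#' @param features Samples x genes numeric matrix (log2(TPM + 1) of the
#'   signature genes), with column names.
#' @param labels01 Binary vector, one per row of \code{features}; both
#'   classes required.
#' @param params One row of \code{\link{hyperparameter_grid}} (or a list
#'   with the same fields).
#' @param seed Integer seed; fitting is deterministic given the seed.
#' @return Object of class \code{"tp53_forest"}; score new samples with
#'   \code{predict}.
#' @export
fit_forest <- function(features, labels01, params, seed = 1L) {
  labels01 <- as.numeric(labels01)
  stopifnot(is.matrix(features), nrow(features) == length(labels01),
            all(labels01 %in% c(0, 1)))
  if (length(unique(labels01)) < 2) stop("labels must contain both classes")
  nodesize <- effective_nodesize(params, nrow(features))
  # a minimum leaf size of `nodesize` bounds the tree at
  # floor(n / nodesize) leaves; at fraction ~1 trees collapse to the root
  # and the score to the label mean
  maxnodes <- max(1L, nrow(features) %/% nodesize)
  set.seed(seed)
  # regression on 0/1 labels is intentional; muffle randomForest's notice
  rf <- withCallingHandlers(
    randomForest::randomForest(
      x = as.data.frame(features), y = labels01,
      ntree = params$n_trees, nodesize = nodesize, maxnodes = maxnodes),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(rf = rf, genes = colnames(features),
                 params = list(n_trees = params$n_trees,
                               min_samples_leaf_fraction =
                                 params$min_samples_leaf_fraction,
                               min_weight_fraction_leaf =
                                 params$min_weight_fraction_leaf,
                               nodesize = nodesize),
                 seed = seed),
            class = "tp53_forest")
}

#' @export
predict.tp53_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$genes, colnames(newdata))
  if (length(missing) > 0)
    stop("features missing genes: ", paste(missing, collapse = ", "))
  scores <- stats::predict(object$rf,
                           as.data.frame(newdata[, object$genes,
                                                 drop = FALSE]))
  pmin(1, pmax(0, unname(scores)))
}

#' Feature importance of a fitted forest
#' @param model A \code{tp53_forest}.
#' @return Named numeric vector (node-purity importance).
#' @export
forest_importance <- function(model) {
  imp <- randomForest::importance(model$rf)[, 1]
  names(imp) <- model$genes
  imp
}

#' Evaluate a hyperparameter grid on a validation set
#'
#' Fits one forest per grid member on the training set and evaluates AUROC
#' and AUPRC on the validation set.  Grid members whose leaf fractions imply
#' the same effective node size give identical fits, so each unique
#' (n_trees, nodesize) pair is fitted once and the result shared — the full
#' grid is evaluated faithfully at a fraction of the fits.
#'
#' @param x_train,y_train Training features (samples x genes) and 0/1
#'   labels.
#' @param x_val,y_val Validation features and labels.
#' @param grid Output of \code{\link{hyperparameter_grid}} (or a subset).
#' @param seed Integer seed used for every fit.
#' @return \code{grid} with added columns \code{auroc}, \code{auprc},
#'   \code{nodesize}.
#' @export
grid_search <- function(x_train, y_train, x_val, y_val, grid, seed = 1L) {
  stopifnot(nrow(grid) > 0)
  grid$nodesize <- vapply(seq_len(nrow(grid)), function(i)
    effective_nodesize(grid[i, ], nrow(x_train)), integer(1))
  key <- paste(grid$n_trees, grid$nodesize)
  uniq <- !duplicated(key)
  res <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    fit <- fit_forest(x_train, y_train, grid[i, ], seed = seed)
    ev <- evaluate_scores(predict(fit, x_val), y_val)
    assign(key[i], c(auroc = ev$auroc, auprc = ev$auprc), envir = res)
  }
  vals <- t(vapply(key, function(k) get(k, envir = res), numeric(2)))
  grid$auroc <- vals[, "auroc"]
  grid$auprc <- vals[, "auprc"]
  grid
}

#' Select the best grid member: AUPRC-first with an AUROC floor
#'
#' Among grid members with validation AUROC above the floor (default 0.8),
#' the member with the highest AUPRC is chosen; ties are broken towards
#' fewer trees, then towards the larger minimum-leaf fraction (stronger
#' regularisation).  If no member clears the floor the overall max-AUPRC
#' member is returned with \code{auroc_floor_met = FALSE} and a warning.
#'
#' @param grid_results Output of \code{\link{grid_search}}.
#' @param auroc_floor AUROC threshold (default 0.8, strict).
#' @return One-row data.frame (the chosen member) with an added logical
#'   column \code{auroc_floor_met}.
#' @export
select_best_model <- function(grid_results, auroc_floor = 0.8) {
  if (nrow(grid_results) == 0) stop("empty grid")
  pool <- grid_results[grid_results$auroc > auroc_floor, , drop = FALSE]
  floor_met <- nrow(pool) > 0
  if (!floor_met) {
    warning("no grid member exceeded the AUROC floor; returning max-AUPRC overall")
    pool <- grid_results
  }
  ord <- order(-pool$auprc, pool$n_trees,
               -pmax(pool$min_samples_leaf_fraction,
                     pool$min_weight_fraction_leaf))
  best <- pool[ord[1], , drop = FALSE]
  best$auroc_floor_met <- floor_met
  rownames(best) <- NULL
  best
}

#' Stratified k-fold cross-validation of a hyperparameter set
#'
#' Folds are stratified by class; the forest is refit on each training fold
#' and AUROC measured on the held-out fold.
#'
#' @param features Samples x genes matrix.
#' @param labels 0/1 vector; must contain at least \code{k} positives.
#' @param params Hyperparameters (one grid row).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and fits.
#' @return Numeric vector of per-fold AUROCs (length \code{k}).
#' @export
cross_validate <- function(features, labels, params, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (sum(labels == 1) < k) stop("fewer positives than folds")
  if (sum(labels == 0) < k) stop("fewer negatives than folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in 0:1) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_forest(features[tr, , drop = FALSE], labels[tr], params,
                      seed = seed + f)
    evaluate_scores(predict(fit, features[!tr, , drop = FALSE]),
                    labels[!tr])$auroc
  }, numeric(1))
}

#' Maximum-sensitivity score cutoff
#'
#' The cutoff is lowered until the last known biallelic sample is included:
#' it equals the minimum score among positives, and prediction uses
#' \code{score >= cutoff}, so sensitivity on the deriving set is exactly
#' 100\% by construction.
#'
#' @param scores Numeric validation scores.
#' @param labels 0/1 validation labels with >= 1 positive.
#' @return Numeric cutoff.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) == 0) stop("no positives to derive a cutoff from")
  min(scores[labels == 1])
}

#' Score a discovery set and threshold at the model cutoff
#'
#' @param model A trained signature model (see
#'   \code{\link{train_signature_model}}) or any list with elements
#'   \code{forest} and \code{cutoff}.
#' @param features Samples x genes matrix covering the model's genes, with
#'   rownames as sample IDs.
#' @param source_set Label recorded in the output (default "discovery").
#' @return data.frame: \code{sample_id}, \code{score},
#'   \code{predicted_label} ("predicted_biallelic"/"predicted_not"),
#'   \code{source_set}.  Empty input gives an empty data.frame.
#' @export
predict_biallelic <- function(model, features, source_set = "discovery") {
  if (is.null(dim(features)) || nrow(features) == 0)
    return(data.frame(sample_id = character(0), score = numeric(0),
                      predicted_label = character(0),
                      source_set = character(0), stringsAsFactors = FALSE))
  scores <- predict(model$forest, features)
  data.frame(sample_id = rownames(features), score = scores,
             predicted_label = ifelse(scores >= model$cutoff,
                                      "predicted_biallelic", "predicted_not"),
             source_set = source_set, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Train, select and calibrate the signature model end-to-end
#'
#' Runs the grid search on the training/validation split, selects the
#' AUPRC-best member with the AUROC floor, refits it on the training set,
#' derives the maximum-sensitivity cutoff from validation scores, and
#' reports the nonzero-importance feature subset as the signature.
#'
#' @param x_train,y_train,x_val,y_val Split feature matrices (samples x
#'   candidate genes) and 0/1 labels.
#' @param grid Hyperparameter grid; default
#'   \code{hyperparameter_grid(ncol(x_train))}.
#' @param seed Integer seed.
#' @param auroc_floor AUROC floor for model selection.
#' @return List of class \code{"signature_model"}: \code{forest},
#'   \code{params}, \code{cutoff}, \code{signature_genes} (nonzero
#'   importance), \code{candidate_genes}, \code{validation}
#'   (model_evaluation), \code{grid_results}, \code{seed}.
#' @export
train_signature_model <- function(x_train, y_train, x_val, y_val,
                                  grid = NULL, seed = 1L,
                                  auroc_floor = 0.8) {
  if (is.null(grid)) grid <- hyperparameter_grid(ncol(x_train))
  gr <- grid_search(x_train, y_train, x_val, y_val, grid, seed = seed)
  best <- select_best_model(gr, auroc_floor = auroc_floor)
  forest <- fit_forest(x_train, y_train, best, seed = seed)
  val_scores <- predict(forest, x_val)
  ev <- evaluate_scores(val_scores, y_val)
  cutoff <- select_cutoff(val_scores, y_val)
  imp <- forest_importance(forest)
  structure(list(forest = forest, params = best, cutoff = cutoff,
                 signature_genes = names(imp)[imp > 0],
                 candidate_genes = colnames(x_train),
                 validation = ev, grid_results = gr, seed = seed),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(paste0("signature model: %d trees, nodesize %d, cutoff %.3f\n",
                     "  %d/%d genes with nonzero importance; ",
                     "validation AUROC %.3f, AUPRC %.3f\n"),
              x$params$n_trees, x$forest$params$nodesize, x$cutoff,
              length(x$signature_genes), length(x$candidate_genes),
              x$validation$auroc, x$validation$auprc))
  invisible(x)
}
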