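# End-to-end orchestration: status calling -> DE/signature -> model
# training, selection and cutoff -> discovery prediction -> mechanism
# assignment -> survival stratification.

#' Pipeline configuration with study defaults
#'
#' Every threshold defaults to the value used throughout the analysis:
#' FC tier 2 for the signature set, 7:3 stratified split, AUPRC-first
#' selection with an AUROC floor of 0.8, the maximum-sensitivity cutoff,
#' and the mechanism thresholds of \code{\link{mechanism_thresholds}}.
#'
#' @param tier DEG fold-change tier for the candidate gene set (default 2).
#' @param split_ratio Training fraction (default 0.7).
#' @param auroc_floor Model-selection AUROC floor (default 0.8).
#' @param cv_folds Cross-validation folds (default 5).
#' @param mechanism Mechanism thresholds list.
#' @param grid Optional hyperparameter grid override (default: full grid
#'   over the candidate gene count).
#' @param min_candidate_genes If the tier set is smaller, fall back to the
#'   next lower tier (default 3, the smallest workable feature set).
#' @param seed Integer seed for split, fits and folds.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(tier = 2, split_ratio = 0.7, auroc_floor = 0.8,
                            cv_folds = 5L,
                            mechanism = mechanism_thresholds(),
                            grid = NULL, min_candidate_genes = 3L,
                            seed = 1L) {
  structure(list(tier = tier, split_ratio = split_ratio,
                 auroc_floor = auroc_floor, cv_folds = cv_folds,
                 mechanism = mechanism, grid = grid,
                 min_candidate_genes = min_candidate_genes,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full hidden-biallelic detection pipeline
#'
#' Calls DNA status for every sample, derives the biallelic-vs-WT DEG
#' signature, trains and selects the regression-forest scorer on a 7:3
#' stratified split, sets the maximum-sensitivity cutoff on the validation
#' set, scores the DNA-monoallelic discovery set, assigns transcriptomic
#' mechanisms to predicted biallelic samples, and stratifies survival by
#' the resulting groups.
#'
#' @param bundle A \code{cohort_bundle} (generated or read from disk).
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV/JSON.
#' @return List of class \code{"run_report"}: \code{status_calls},
#'   \code{counts}, \code{degs}, \code{candidate_genes}, \code{model},
#'   \code{cv_auroc}, \code{validation} (incl. sensitivity/specificity at
#'   the cutoff), \code{predictions} (discovery set), \code{mechanisms},
#'   \code{survival}, \code{config}.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle") || is.list(bundle))
  samples <- colnames(bundle$expression)
  id_mismatch <- setdiff(bundle$baf$sample_id, samples)
  if (length(id_mismatch) > 0)
    stop("sample IDs absent from expression matrix: ",
         paste(utils::head(id_mismatch, 5), collapse = ", "))

  ## stage 1: DNA status
  calls <- call_tp53_status(samples, bundle$mutations, bundle$segments,
                            bundle$baf)
  known_biallelic <- calls$sample_id[calls$status == "biallelic"]
  known_mono <- calls$sample_id[calls$status == "monoallelic"]
  known_wt <- calls$sample_id[calls$status == "WT"]

  ## stage 2: DE signature between known biallelic and WT
  degs <- differential_expression(bundle$expression, known_biallelic,
                                  known_wt)
  tiers <- c(3, 2.5, 2, 1.5)
  tiers <- tiers[tiers <= config$tier]
  candidate_genes <- character(0)
  for (tr in tiers) {
    candidate_genes <- select_signature_set(degs, tr)
    if (length(candidate_genes) >= config$min_candidate_genes) break
  }
  if (length(candidate_genes) < config$min_candidate_genes)
    stop("fewer than ", config$min_candidate_genes,
         " signature genes at any tier <= ", config$tier)

  log_expr <- t(log_transform(bundle$expression[candidate_genes, ,
                                                drop = FALSE]))

  ## stage 3: split, grid search, selection, cutoff
  model_samples <- c(known_biallelic, known_wt)
  labels <- as.integer(model_samples %in% known_biallelic)
  split <- stratified_split(model_samples, labels,
                            ratio = config$split_ratio, seed = config$seed)
  y <- stats::setNames(labels, model_samples)
  grid <- if (is.null(config$grid))
    hyperparameter_grid(length(candidate_genes)) else config$grid
  model <- train_signature_model(
    log_expr[split$training, , drop = FALSE], y[split$training],
    log_expr[split$validation, , drop = FALSE], y[split$validation],
    grid = grid, seed = config$seed, auroc_floor = config$auroc_floor)

  cv_auroc <- cross_validate(log_expr[model_samples, , drop = FALSE],
                             labels, model$params, k = config$cv_folds,
                             seed = config$seed)

  val_pred <- predict_biallelic(model,
                                log_expr[split$validation, , drop = FALSE],
                                source_set = "validation")
  val_truth <- y[split$validation]
  val_pos <- val_pred$predicted_label == "predicted_biallelic"
  sensitivity <- sum(val_pos & val_truth == 1) / sum(val_truth == 1)
  specificity <- sum(!val_pos & val_truth == 0) / sum(val_truth == 0)

  ## stage 4: discovery prediction on DNA-monoallelic samples
  discovery <- predict_biallelic(model,
                                 log_expr[known_mono, , drop = FALSE],
                                 source_set = "discovery")
  predicted_biallelic <- discovery$sample_id[
    discovery$predicted_label == "predicted_biallelic"]
  predicted_mono <- setdiff(known_mono, predicted_biallelic)

  ## stage 5: mechanisms for predicted biallelic, DNA-monoallelic samples
  mechanisms <- assign_mechanisms(
    predicted_biallelic, bundle$splicing, bundle$normal_ids,
    expression = bundle$expression,
    normal_expression = bundle$normal_expression,
    mutations = bundle$mutations, thresholds = config$mechanism)

  ## stage 6: survival by refined grouping
  grp <- stats::setNames(rep("WT", length(samples)), samples)
  grp[known_mono] <- "predicted_monoallelic"
  grp[predicted_biallelic] <- "predicted_biallelic"
  grp[known_biallelic] <- "known_biallelic"
  clin <- bundle$clinical
  clin$group <- grp[clin$sample_id]
  records <- derive_endpoints(clin)
  surv <- lapply(c("PFS", "OS"), function(ep) {
    rec <- records[records$endpoint == ep, , drop = FALSE]
    km <- lapply(split(rec, rec$group), function(r)
      km_estimate(r$time, r$event))
    biall <- rec[rec$group %in% c("known_biallelic", "predicted_biallelic"), ]
    mono <- rec[rec$group == "predicted_monoallelic", ]
    wt <- rec[rec$group == "WT", ]
    lr_vs_mono <- if (nrow(biall) > 0 && nrow(mono) > 0)
      logrank_test(biall$time, biall$event, mono$time, mono$event) else NULL
    lr_vs_wt <- if (nrow(biall) > 0 && nrow(wt) > 0)
      logrank_test(biall$time, biall$event, wt$time, wt$event) else NULL
    list(endpoint = ep,
         medians = vapply(km, function(k) k$median, numeric(1)),
         km = km, logrank_combined_vs_mono = lr_vs_mono,
         logrank_combined_vs_wt = lr_vs_wt)
  })
  names(surv) <- c("PFS", "OS")

  counts <- list(n = length(samples),
                 known_biallelic = length(known_biallelic),
                 known_monoallelic = length(known_mono),
                 known_wt = length(known_wt),
                 training = length(split$training),
                 validation = length(split$validation),
                 discovery = length(known_mono),
                 predicted_biallelic = length(predicted_biallelic),
                 predicted_not = length(predicted_mono))

  report <- structure(list(status_calls = calls, counts = counts,
                           degs = degs, candidate_genes = candidate_genes,
                           model = model, cv_auroc = cv_auroc,
                           validation = list(predictions = val_pred,
                                             sensitivity = sensitivity,
                                             specificity = specificity,
                                             auroc = model$validation$auroc,
                                             auprc = model$validation$auprc),
                           split = split,
                           predictions = discovery,
                           mechanisms = mechanisms, survival = surv,
                           config = config),
                      class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0(
    "pipeline run: %d samples (%d biallelic / %d monoallelic / %d WT)\n",
    "  candidate genes: %d; signature genes (nonzero importance): %d\n",
    "  validation AUROC %.3f, AUPRC %.3f; cutoff %.3f ",
    "(sens %.1f%%, spec %.1f%%)\n",
    "  discovery: %d/%d predicted biallelic (%.1f%%)\n"),
    ct$n, ct$known_biallelic, ct$known_monoallelic, ct$known_wt,
    length(x$candidate_genes), length(x$model$signature_genes),
    x$validation$auroc, x$validation$auprc, x$model$cutoff,
    100 * x$validation$sensitivity, 100 * x$validation$specificity,
    ct$predicted_biallelic, ct$discovery,
    100 * ct$predicted_biallelic / max(1, ct$discovery)))
  invisible(x)
}

#' Write a run report's tables to a directory
#' @param report A \code{run_report}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(report$status_calls, p("status_calls.tsv"))
  .write_tsv(report$degs, p("degs.tsv"))
  .write_tsv(rbind(report$validation$predictions, report$predictions),
             p("predictions.tsv"))
  .write_tsv(report$mechanisms, p("mechanisms.tsv"))
  surv_summary <- lapply(report$survival, function(s) {
    list(medians = lapply(s$medians, function(m)
      if (is.na(m)) "not reached" else m),
         logrank_combined_vs_mono = if (!is.null(s$logrank_combined_vs_mono))
           list(statistic = s$logrank_combined_vs_mono$statistic,
                p = s$logrank_combined_vs_mono$p),
         logrank_combined_vs_wt = if (!is.null(s$logrank_combined_vs_wt))
           list(statistic = s$logrank_combined_vs_wt$statistic,
                p = s$logrank_combined_vs_wt$p))
  })
  jsonlite::write_json(list(
    counts = report$counts,
    model = list(n_trees = report$model$params$n_trees,
                 min_samples_leaf_fraction =
                   report$model$params$min_samples_leaf_fraction,
                 min_weight_fraction_leaf =
                   report$model$params$min_weight_fraction_leaf,
                 cutoff = report$model$cutoff,
                 auroc = report$validation$auroc,
                 auprc = report$validation$auprc,
                 signature_genes = report$model$signature_genes,
                 cv_auroc = report$cv_auroc),
    survival = surv_summary), p("report.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
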