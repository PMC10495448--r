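# ROC / precision-recall evaluation of a continuous scorer against binary
# labels, computed by an explicit threshold sweep so the curves and areas
# are exactly reproducible.

#' Evaluate classification scores against binary labels
#'
#' Sweeps thresholds over the unique score values (descending; samples with
#' tied scores enter together).  AUROC is the trapezoidal area under the ROC
#' curve, which equals the Mann-Whitney concordance probability (ties
#' counted 1/2).  AUPRC uses step integration of precision over recall
#' (the "average precision" convention): sum over thresholds of
#' (recall_i - recall_{i-1}) * precision_i, without interpolation.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return List of class \code{"model_evaluation"}: \code{roc} (data.frame
#'   fpr, tpr), \code{pr} (data.frame recall, precision), \code{auroc},
#'   \code{auprc}.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each unique threshold (ties grouped)
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- (grp_end) - tp
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  precision <- tp / (tp + fp)

  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)

  pr <- data.frame(recall = c(0, tpr), precision = c(1, precision))
  auprc <- sum(diff(c(0, tpr)) * precision)

  structure(list(roc = roc, pr = pr, auroc = auroc, auprc = auprc),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("model evaluation: AUROC = %.4f, AUPRC = %.4f (%d thresholds)\n",
              x$auroc, x$auprc, nrow(x$roc) - 1L))
  invisible(x)
}

#' Pearson chi-square enrichment test on a 2x2 table
#'
#' Chi-square test of independence without continuity correction (1 df),
#' used to test enrichment of a genomic marker among predicted biallelic
#' samples.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with \code{statistic} and \code{p}.
#' @export
enrichment_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}
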