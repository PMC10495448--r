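# Differential expression on the log2(TPM + 1) scale and the fold-change
# tiered signature gene sets.

#' Log2(TPM + 1) transform
#'
#' @param tpm Non-negative numeric matrix or vector of TPM values.
#' @return Same shape, elementwise \code{log2(x + 1)}.
#' @export
log_transform <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  log2(tpm + 1)
}

#' Inverse of \code{log_transform}
#' @param x Transformed values.
#' @return TPM on the linear scale.
#' @export
inv_log_transform <- function(x) 2^x - 1

#' Differential expression between biallelic and wild-type samples
#'
#' Per gene, a Welch two-sample t-test on log2(TPM + 1) values with
#' Benjamini-Hochberg FDR across all tested genes.  Fold-change is computed
#' on the linear scale as (mean TPM_biallelic + 1) / (mean TPM_WT + 1); the
#' +1 stabiliser matches the transform's pseudocount.  A gene is significant
#' when FDR < \code{fdr_max}, FC > \code{fc_up} or FC < \code{fc_down}, and
#' the mean log2(TPM + 1) exceeds \code{expr_min} in at least one group.
#'
#' @param tpm Genes x samples TPM matrix with row and column names.
#' @param group_biallelic,group_wt Disjoint character vectors of sample IDs,
#'   each of size >= 2.
#' @param fc_up,fc_down,fdr_max,expr_min Significance filter thresholds
#'   (defaults 1.4, 0.71, 0.05, 1).
#' @return data.frame with one row per gene: \code{gene}, \code{fc},
#'   \code{log2fc}, \code{p}, \code{fdr}, \code{mean_log_biallelic},
#'   \code{mean_log_wt}, \code{significant}.
#' @export
differential_expression <- function(tpm, group_biallelic, group_wt,
                                    fc_up = 1.4, fc_down = 0.71,
                                    fdr_max = 0.05, expr_min = 1) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (length(intersect(group_biallelic, group_wt)) > 0)
    stop("groups overlap")
  if (length(group_biallelic) < 2 || length(group_wt) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_biallelic, group_wt), colnames(tpm))
  if (length(missing) > 0)
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))

  xa <- tpm[, group_biallelic, drop = FALSE]
  xw <- tpm[, group_wt, drop = FALSE]
  la <- log_transform(xa)
  lw <- log_transform(xw)
  na <- ncol(la); nw <- ncol(lw)

  ma <- rowMeans(la); mw <- rowMeans(lw)
  va <- rowSums((la - ma)^2) / (na - 1)
  vw <- rowSums((lw - mw)^2) / (nw - 1)

  se2 <- va / na + vw / nw
  tstat <- (ma - mw) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vw / nw)^2 / (nw - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate genes: no variance in either group
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mw[zero], 1, 0)
  fdr <- stats::p.adjust(p, method = "BH")

  fc <- (rowMeans(xa) + 1) / (rowMeans(xw) + 1)
  sig <- fdr < fdr_max & (fc > fc_up | fc < fc_down) &
         (ma > expr_min | mw > expr_min)
  data.frame(gene = rownames(tpm), fc = fc, log2fc = log2(fc), p = p,
             fdr = fdr, mean_log_biallelic = ma, mean_log_wt = mw,
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change tiered signature gene sets
#'
#' From the significant DEGs, select the genes whose fold-change reaches a
#' tier threshold in either direction (FC >= tier or FC <= 1/tier, so a
#' gene at exactly the tier value belongs to that tier).  Tiers are nested:
#' FC3 is a subset of FC2.5 of FC2 of FC1.5.
#'
#' @param degs Output of \code{\link{differential_expression}}.
#' @param tier One of 1.5, 2, 2.5, 3.
#' @return Character vector of gene names.
#' @export
select_signature_set <- function(degs, tier = 2) {
  if (!tier %in% c(1.5, 2, 2.5, 3)) stop("unknown tier: ", tier)
  sig <- degs[degs$significant, , drop = FALSE]
  sig$gene[sig$fc >= tier | sig$fc <= 1 / tier]
}
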