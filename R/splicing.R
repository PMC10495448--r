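# Aberrant TP53 splicing: PSI/dPSI quantification, isoform classification
# and imbalance, splicing-regulator ranking, splice-site-mutation/VAF
# association, and per-sample mechanism assignment.

#' Percent spliced in (PSI) from intron and junction read counts
#'
#' PSI = intron_reads / (junction_reads + intron_reads).  When both counts
#' are zero PSI is undefined and returned as NA.
#'
#' @param intron_reads,junction_reads Non-negative counts (vectorised).
#' @return Numeric PSI in [0, 1], NA where undefined.
#' @export
#' @examples
#' compute_psi(10, 30)  # 0.25
compute_psi <- function(intron_reads, junction_reads) {
  if (any(intron_reads < 0) || any(junction_reads < 0))
    stop("read counts must be non-negative")
  total <- intron_reads + junction_reads
  ifelse(total == 0, NA_real_, intron_reads / total)
}

#' Delta PSI between normal samples and a tumor sample or group
#'
#' dPSI = mean(PSI_normal) - mean(PSI_tumor).  More inclusion in the tumor
#' gives a negative dPSI.
#'
#' @param psi_normals Numeric vector of PSI values in normal samples.
#' @param psi_tumor PSI of the tumor sample, or a vector for a group.
#' @return List: \code{mean_psi_normal}, \code{mean_psi_tumor}, \code{dpsi}.
#' @export
compute_dpsi <- function(psi_normals, psi_tumor) {
  mn <- mean(psi_normals, na.rm = TRUE)
  mt <- mean(psi_tumor, na.rm = TRUE)
  if (is.nan(mn) || is.nan(mt))
    stop("all PSI values undefined on one side")
  list(mean_psi_normal = mn, mean_psi_tumor = mt, dpsi = mn - mt)
}

#' p53 isoform class labels
#'
#' C-terminal types alpha/beta/gamma crossed with N-terminal length classes
#' TA (full length), d40, d133, d160.
#' @return Character vector of the 12 class labels, e.g. "TA_alpha".
#' @export
isoform_classes <- function() {
  as.vector(outer(c("TA", "d40", "d133", "d160"),
                  c("alpha", "beta", "gamma"), paste, sep = "_"))
}

#' Classify a transcript into a p53 isoform class
#'
#' The C-terminal type follows the cryptic-exon status between exons 9 and
#' 10 (no cryptic exon: alpha; cryptic form 1: beta; cryptic form 2: gamma)
#' and the N-terminal length class follows the start site.  Both are
#' supplied through a class map; transcripts absent from the map are
#' reported as unclassified (NA).
#'
#' @param transcript_id Character vector of transcript IDs.
#' @param class_map data.frame with columns \code{transcript_id},
#'   \code{cryptic_exon_form} (0, 1 or 2) and \code{length_class}
#'   ("TA", "d40", "d133", "d160").
#' @return Character vector of isoform classes ("TA_alpha", ...), NA for
#'   unclassified transcripts.
#' @export
classify_transcript <- function(transcript_id, class_map) {
  stopifnot(all(c("transcript_id", "cryptic_exon_form", "length_class")
                %in% names(class_map)))
  i <- match(transcript_id, class_map$transcript_id)
  ctype <- c("alpha", "beta", "gamma")[class_map$cryptic_exon_form[i] + 1L]
  out <- paste(class_map$length_class[i], ctype, sep = "_")
  out[is.na(i)] <- NA_character_
  out
}

#' High-risk isoform imbalance ratio: (TA-beta + TA-gamma) / TA-alpha
#'
#' Dominant expression of the beta/gamma isoforms over full-length alpha is
#' a high-risk marker; a ratio above 1 indicates the imbalance.
#'
#' @param class_tpm Named numeric vector of per-class TPM containing at
#'   least "TA_alpha", "TA_beta", "TA_gamma".
#' @return Numeric ratio; \code{Inf} when TA_alpha is 0 with a nonzero
#'   numerator; NA when all three classes are 0.
#' @export
isoform_imbalance_ratio <- function(class_tpm) {
  need <- c("TA_alpha", "TA_beta", "TA_gamma")
  stopifnot(all(need %in% names(class_tpm)))
  a <- class_tpm[["TA_alpha"]]
  bg <- class_tpm[["TA_beta"]] + class_tpm[["TA_gamma"]]
  if (a == 0 && bg == 0) return(NA_real_)
  if (a == 0) return(Inf)
  bg / a
}

#' Rank candidate splicing regulators by correlation with dPSI
#'
#' Spearman correlation (average ranks for ties) between each gene's
#' expression and the per-sample cryptic-exon dPSI, sorted by |rho|
#' descending.
#'
#' @param expr Genes x samples numeric matrix (log2(TPM + 1) or TPM).
#' @param dpsi Named numeric vector of per-sample dPSI; >= 5 defined values
#'   required and the vector must not be constant.
#' @return data.frame: \code{gene}, \code{rho}, \code{p}, \code{rank}.
#' @export
rank_splicing_regulators <- function(expr, dpsi) {
  common <- intersect(colnames(expr), names(dpsi))
  dpsi <- dpsi[common]
  keep <- !is.na(dpsi)
  if (sum(keep) < 5) stop("need >= 5 samples with defined dPSI")
  dpsi <- dpsi[keep]
  if (stats::sd(dpsi) == 0) stop("dPSI vector is constant")
  x <- expr[, names(dpsi), drop = FALSE]
  res <- t(apply(x, 1, function(g) {
    if (stats::sd(g) == 0) return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(g, dpsi, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }))
  out <- data.frame(gene = rownames(x), rho = res[, "rho"], p = res[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), out$gene, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Association between splice-site mutation VAF and splicing level
#'
#' Spearman correlation between paired VAF and PSI observations, plus a
#' per-sample table flagging low-VAF samples without aberrant splicing
#' (VAF < \code{vaf_floor} and PSI < \code{psi_min}).
#'
#' @param vafs,psi_values Paired numeric vectors, n >= 3.
#' @param vaf_floor,psi_min Flag thresholds (defaults 0.2 and 0.2).
#' @return List: \code{rho}, \code{p}, \code{table} (vaf, psi,
#'   low_vaf_no_splicing).
#' @export
vaf_splicing_association <- function(vafs, psi_values,
                                     vaf_floor = 0.2, psi_min = 0.2) {
  stopifnot(length(vafs) == length(psi_values))
  if (length(vafs) < 3) stop("need >= 3 paired observations")
  if (stats::sd(psi_values) == 0) {
    rho <- 0; p <- 1  # constant PSI carries no ordering information
  } else {
    ct <- suppressWarnings(
      stats::cor.test(vafs, psi_values, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(rho = rho, p = p,
       table = data.frame(vaf = vafs, psi = psi_values,
                          low_vaf_no_splicing = vafs < vaf_floor &
                            psi_values < psi_min))
}

#' Default mechanism-assignment thresholds
#'
#' \code{dpsi_min}: |dPSI| for calling cryptic-exon inclusion;
#' \code{psi_min}: PSI for calling a novel retained intron (with ~0 PSI in
#' normals); \code{expr_floor}: log2(TPM+1) below which total TP53
#' expression is "low"; \code{log2fc_floor}: log2 fold-change versus
#' normals below which expression is "low"; \code{vaf_floor}: minimum
#' splice-site-mutation VAF to implicate the mutation;
#' \code{normal_psi_max}: maximum mean normal PSI for an event to count as
#' novel.
#' @return Named list of thresholds.
#' @export
mechanism_thresholds <- function() {
  list(dpsi_min = 0.2, psi_min = 0.2, expr_floor = 1.0,
       log2fc_floor = -0.8, vaf_floor = 0.2, normal_psi_max = 0.05)
}

#' Assign transcriptomic second-hit mechanism labels to one sample
#'
#' For a sample predicted biallelic by the signature model but monoallelic
#' at the DNA level, assigns every supported mechanism label:
#' \itemize{
#'   \item \code{cryptic_exon_inclusion}: cryptic-exon dPSI <= -dpsi_min;
#'   \item \code{retained_intron}: a retained-intron event with PSI >=
#'     psi_min while normals are ~0;
#'   \item \code{low_total_expression}: gene log2(TPM+1) <= expr_floor or
#'     log2FC versus normals <= log2fc_floor;
#'   \item \code{splice_site_mutation_driven}: a splice-site mutation with
#'     VAF >= vaf_floor co-occurring with any splicing label;
#'   \item \code{unexplained}: none of the above.
#' }
#'
#' @param sample_id Sample identifier.
#' @param dpsi_cryptic Cryptic-exon dPSI versus normals (NA if the layer is
#'   missing).
#' @param ri_events data.frame of retained-intron events for the sample
#'   with columns \code{psi} and \code{normal_psi} (mean PSI in normals);
#'   may be empty or NULL.
#' @param gene_log_expr TP53 gene-level log2(TPM + 1) (NA if missing).
#' @param gene_log2fc_vs_normal log2 fold-change of TP53 expression versus
#'   the normal mean (NA if missing).
#' @param splice_mutation_vafs Numeric vector of splice-site-mutation VAFs
#'   for the sample (may be empty).
#' @param thresholds See \code{\link{mechanism_thresholds}}.
#' @return List of class \code{"mechanism_call"}: \code{sample_id},
#'   \code{labels} (character vector), \code{evidence} (named values),
#'   \code{missing_layers} (character vector of absent data layers).
#' @export
assign_mechanism <- function(sample_id, dpsi_cryptic = NA, ri_events = NULL,
                             gene_log_expr = NA,
                             gene_log2fc_vs_normal = NA,
                             splice_mutation_vafs = numeric(0),
                             thresholds = mechanism_thresholds()) {
  th <- utils::modifyList(mechanism_thresholds(), as.list(thresholds))
  labels <- character(0)
  missing_layers <- character(0)

  if (is.na(dpsi_cryptic)) missing_layers <- c(missing_layers, "cryptic_exon_dpsi")
  else if (dpsi_cryptic <= -th$dpsi_min)
    labels <- c(labels, "cryptic_exon_inclusion")

  ri_hit <- FALSE
  if (is.null(ri_events)) missing_layers <- c(missing_layers, "retained_introns")
  else if (nrow(ri_events) > 0) {
    ri_hit <- any(ri_events$psi >= th$psi_min &
                  ri_events$normal_psi <= th$normal_psi_max, na.rm = TRUE)
    if (ri_hit) labels <- c(labels, "retained_intron")
  }

  if (is.na(gene_log_expr) && is.na(gene_log2fc_vs_normal))
    missing_layers <- c(missing_layers, "gene_expression")
  else if ((!is.na(gene_log_expr) && gene_log_expr <= th$expr_floor) ||
           (!is.na(gene_log2fc_vs_normal) &&
            gene_log2fc_vs_normal <= th$log2fc_floor))
    labels <- c(labels, "low_total_expression")

  has_splicing <- any(labels %in% c("cryptic_exon_inclusion", "retained_intron"))
  if (length(splice_mutation_vafs) > 0 &&
      any(splice_mutation_vafs >= th$vaf_floor) && has_splicing)
    labels <- c(labels, "splice_site_mutation_driven")

  if (length(labels) == 0) labels <- "unexplained"
  structure(list(sample_id = sample_id, labels = labels,
                 evidence = list(dpsi = dpsi_cryptic,
                                 max_ri_psi = if (!is.null(ri_events) &&
                                                  nrow(ri_events) > 0)
                                   max(ri_events$psi, na.rm = TRUE) else NA,
                                 gene_log_expr = gene_log_expr,
                                 gene_log2fc = gene_log2fc_vs_normal,
                                 max_splice_vaf =
                                   if (length(splice_mutation_vafs) > 0)
                                     max(splice_mutation_vafs) else NA),
                 missing_layers = missing_layers),
            class = "mechanism_call")
}

#' Assign mechanisms across a cohort of predicted-biallelic samples
#'
#' Convenience wrapper: computes per-sample cryptic-exon dPSI and
#' retained-intron PSI from a long splicing table (tumor + normal samples),
#' pulls TP53 expression and splice-site mutations, and calls
#' \code{\link{assign_mechanism}} per sample.
#'
#' @param sample_ids Samples to call (typically predicted biallelic,
#'   DNA-monoallelic).
#' @param splicing Long data.frame: \code{sample_id}, \code{event_id},
#'   \code{event_class} ("cryptic_exon", "retained_intron",
#'   "alt_3prime_site"), \code{intron_reads}, \code{junction_reads}.
#' @param normal_ids Sample IDs in \code{splicing} that are normal
#'   controls.
#' @param expression TPM matrix (genes x samples) containing a "TP53" row,
#'   or NULL.
#' @param normal_expression TPM matrix for normals (used for the log2FC
#'   baseline), or NULL.
#' @param mutations Mutation data.frame (see
#'   \code{\link{call_tp53_status}}), or NULL.
#' @param thresholds See \code{\link{mechanism_thresholds}}.
#' @return data.frame: one row per sample with \code{labels} collapsed by
#'   ";" plus the supporting values; the per-sample call objects are in
#'   \code{attr(, "calls")}.
#' @export
assign_mechanisms <- function(sample_ids, splicing, normal_ids,
                              expression = NULL, normal_expression = NULL,
                              mutations = NULL,
                              thresholds = mechanism_thresholds()) {
  splicing$psi <- compute_psi(splicing$intron_reads, splicing$junction_reads)
  norm <- splicing[splicing$sample_id %in% normal_ids, , drop = FALSE]
  normal_mean_psi <- tapply(norm$psi, norm$event_id, mean, na.rm = TRUE)

  tp53_log <- if (!is.null(expression) && "TP53" %in% rownames(expression))
    log_transform(expression["TP53", ]) else NULL
  normal_tp53_mean <- if (!is.null(normal_expression) &&
                          "TP53" %in% rownames(normal_expression))
    mean(log_transform(normal_expression["TP53", ])) else NA

  calls <- lapply(sample_ids, function(s) {
    ev <- splicing[splicing$sample_id == s, , drop = FALSE]
    ce <- ev[ev$event_class == "cryptic_exon", , drop = FALSE]
    dpsi <- NA_real_
    if (nrow(ce) > 0) {
      nm <- normal_mean_psi[as.character(ce$event_id[1])]
      if (!is.na(nm) && !is.na(ce$psi[1])) dpsi <- unname(nm - ce$psi[1])
    }
    ri <- ev[ev$event_class == "retained_intron", , drop = FALSE]
    ri_df <- if (nrow(ri) > 0)
      data.frame(psi = ri$psi,
                 normal_psi = unname(normal_mean_psi[as.character(ri$event_id)]))
    else data.frame(psi = numeric(0), normal_psi = numeric(0))
    gl <- if (!is.null(tp53_log) && s %in% names(tp53_log))
      unname(tp53_log[s]) else NA
    gfc <- if (!is.na(normal_tp53_mean) && !is.na(gl)) gl - normal_tp53_mean
    else NA
    vafs <- if (!is.null(mutations))
      mutations$vaf[mutations$sample_id == s &
                    mutations$consequence == "splice_site"] else numeric(0)
    assign_mechanism(s, dpsi_cryptic = dpsi, ri_events = ri_df,
                     gene_log_expr = gl, gene_log2fc_vs_normal = gfc,
                     splice_mutation_vafs = vafs, thresholds = thresholds)
  })
  out <- data.frame(
    sample_id = sample_ids,
    labels = vapply(calls, function(x) paste(x$labels, collapse = ";"), ""),
    dpsi = vapply(calls, function(x) as.numeric(x$evidence$dpsi), 0),
    max_ri_psi = vapply(calls, function(x) as.numeric(x$evidence$max_ri_psi), 0),
    gene_log_expr = vapply(calls, function(x)
      as.numeric(x$evidence$gene_log_expr), 0),
    gene_log2fc = vapply(calls, function(x)
      as.numeric(x$evidence$gene_log2fc), 0),
    max_splice_vaf = vapply(calls, function(x)
      as.numeric(x$evidence$max_splice_vaf), 0),
    stringsAsFactors = FALSE)
  attr(out, "calls") <- calls
  out
}
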