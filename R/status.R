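# DNA-level TP53 status calling: CNV categorisation, BAF folding, LOH and the
# biallelic/monoallelic/wild-type decision rules.

#' Fold a raw B-allele frequency onto [0, 0.5]
#'
#' B-allele frequencies are symmetric around 0.5 (either allele may be the
#' "B" allele), so allelic imbalance is measured on the folded scale
#' \code{min(baf, 1 - baf)}: 0.5 means balanced alleles, 0 means complete
#' loss of heterozygosity.
#'
#' @param raw_baf Numeric vector of B-allele frequencies in [0, 1].
#' @return Numeric vector of folded values in [0, 0.5].
#' @export
#' @examples
#' fold_baf(c(0.5, 0.9, 0))
fold_baf <- function(raw_baf) {
  stopifnot(is.numeric(raw_baf))
  if (any(!is.finite(raw_baf)) || any(raw_baf < 0 | raw_baf > 1))
    stop("raw_baf must be finite and within [0, 1]")
  pmin(raw_baf, 1 - raw_baf)
}

#' Call loss of heterozygosity from a folded B-allele frequency
#'
#' LOH is called when the folded BAF falls strictly below 0.25, the midpoint
#' between balanced alleles (0.5) and complete loss (0).
#'
#' @param folded_baf Numeric vector of folded BAFs in [0, 0.5].
#' @param threshold LOH threshold; default 0.25, compared strictly (\code{<}).
#' @return Logical vector: \code{TRUE} where LOH is called.
#' @export
call_loh <- function(folded_baf, threshold = 0.25) {
  stopifnot(is.numeric(folded_baf))
  if (any(!is.finite(folded_baf)) || any(folded_baf < 0 | folded_baf > 0.5))
    stop("folded_baf must be finite and within [0, 0.5]")
  folded_baf < threshold
}

#' CNV category levels, ordered from gain to loss
#' @export
cnv_categories <- function() {
  c("amplification", "gain", "neutral", "deletion", "deep_deletion")
}

#' Categorise a copy-number log2 fold-change
#'
#' Categories: amplification (log2FC >= 0.8), gain ([0.2, 0.8)), neutral
#' ((-0.2, 0.2)), deletion ([-2.0, -0.2]), deep deletion (< -2.0).  Boundary
#' assignment respects the strict/inclusive signs of the defining thresholds
#' (">= 0.8", "< -2.0"); the remaining boundaries are assigned so the five
#' categories partition the real line.
#'
#' @param log2fc Numeric vector of copy-number log2 fold-changes.
#' @return Factor with levels \code{cnv_categories()}.
#' @export
#' @examples
#' categorize_cnv(c(0.9, -1.0, 0, -2.5))
categorize_cnv <- function(log2fc) {
  stopifnot(is.numeric(log2fc))
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  out <- ifelse(log2fc >= 0.8, "amplification",
         ifelse(log2fc >= 0.2, "gain",
         ifelse(log2fc > -0.2, "neutral",
         ifelse(log2fc >= -2.0, "deletion", "deep_deletion"))))
  factor(out, levels = cnv_categories())
}

#' Summarise segment-level CNV calls to a single gene-level log2FC
#'
#' Among segments on the gene's chromosome that overlap the gene interval,
#' the log2FC of the segment with the largest overlap is returned; ties on
#' overlap length are broken towards the more extreme |log2FC|.  With no
#' overlapping segment the gene is treated as copy-neutral (0).
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive, SEG convention) and \code{log2fc}.
#' @param gene_chrom,gene_start,gene_end Gene interval (1-based inclusive).
#' @return Single numeric log2 fold-change.
#' @export
gene_level_cnv <- function(segments, gene_chrom, gene_start, gene_end) {
  if (nrow(segments) == 0) return(0)
  stopifnot(all(c("chrom", "start", "end", "log2fc") %in% names(segments)))
  if (any(segments$start > segments$end)) stop("malformed segment: start > end")
  if (gene_start > gene_end) stop("malformed gene interval: start > end")
  seg <- segments[segments$chrom == gene_chrom, , drop = FALSE]
  if (nrow(seg) == 0) return(0)
  ov <- pmin(seg$end, gene_end) - pmax(seg$start, gene_start) + 1
  seg <- seg[ov > 0, , drop = FALSE]
  ov <- ov[ov > 0]
  if (length(ov) == 0) return(0)
  best <- which(ov == max(ov))
  if (length(best) > 1) best <- best[which.max(abs(seg$log2fc[best]))]
  seg$log2fc[best]
}

#' Consequence classes that count as TP53-inactivating mutations
#' @export
eligible_consequences <- function() {
  c("missense", "nonsense", "frameshift", "splice_site")
}

#' Classify one sample's TP53 DNA status
#'
#' Biallelic inactivation requires evidence against both alleles: deep
#' deletion, mutation plus deletion, or mutation plus LOH.  A single hit
#' (mutation, deletion-class CNV, or LOH) is monoallelic; otherwise the
#' sample is wild-type.  The evidence rule records the first matching rule
#' in that priority order.
#'
#' @param n_mutations Number of eligible TP53 mutations in the sample
#'   (missense, nonsense, frameshift or splice-site; no VAF floor).
#' @param cnv_category One of \code{cnv_categories()}.
#' @param has_loh Logical LOH flag.
#' @return List with \code{status} ("biallelic", "monoallelic" or "WT") and
#'   \code{evidence_rule} ("deep_deletion", "mutation+deletion",
#'   "mutation+LOH", "mono_mutation", "mono_deletion", "mono_LOH", "none").
#' @export
classify_tp53_status <- function(n_mutations, cnv_category, has_loh) {
  cnv_category <- as.character(cnv_category)
  stopifnot(cnv_category %in% cnv_categories(),
            is.logical(has_loh), length(has_loh) == 1L,
            n_mutations >= 0)
  has_mut <- n_mutations >= 1
  if (cnv_category == "deep_deletion")
    return(list(status = "biallelic", evidence_rule = "deep_deletion"))
  if (has_mut && cnv_category == "deletion")
    return(list(status = "biallelic", evidence_rule = "mutation+deletion"))
  if (has_mut && has_loh)
    return(list(status = "biallelic", evidence_rule = "mutation+LOH"))
  if (has_mut)
    return(list(status = "monoallelic", evidence_rule = "mono_mutation"))
  if (cnv_category == "deletion")
    return(list(status = "monoallelic", evidence_rule = "mono_deletion"))
  if (has_loh)
    return(list(status = "monoallelic", evidence_rule = "mono_LOH"))
  list(status = "WT", evidence_rule = "none")
}

#' Default TP53 locus (hg38, 1-based inclusive)
#' @export
tp53_interval <- function() {
  list(chrom = "chr17", start = 7668402L, end = 7687550L)
}

#' Call TP53 status for every sample in a cohort
#'
#' Combines the per-sample mutation table, copy-number segments and folded
#' B-allele frequency into one \code{TP53StatusCall} row per sample.
#'
#' @param samples Character vector of sample IDs to call.
#' @param mutations data.frame with columns \code{sample_id}, \code{gene},
#'   \code{consequence}, \code{vaf} (other MAF-style columns are ignored).
#' @param segments data.frame of CNV segments (\code{sample_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{log2fc}).
#' @param baf data.frame with \code{sample_id}, \code{folded_baf}.
#' @param gene Gene symbol to restrict mutations to (default "TP53").
#' @param gene_interval List with \code{chrom}, \code{start}, \code{end};
#'   default \code{tp53_interval()}.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{status}, \code{cnv_category}, \code{log2fc}, \code{folded_baf},
#'   \code{has_mutation}, \code{has_loh}, \code{evidence_rule}.
#' @export
call_tp53_status <- function(samples, mutations, segments, baf,
                             gene = "TP53", gene_interval = tp53_interval()) {
  stopifnot(length(samples) > 0, !anyDuplicated(samples))
  mut <- mutations[mutations$gene == gene &
                   mutations$consequence %in% eligible_consequences(), ,
                   drop = FALSE]
  out <- lapply(samples, function(s) {
    nmut <- sum(mut$sample_id == s)
    seg_s <- segments[segments$sample_id == s, , drop = FALSE]
    lfc <- gene_level_cnv(seg_s, gene_interval$chrom,
                          gene_interval$start, gene_interval$end)
    cat_s <- as.character(categorize_cnv(lfc))
    b <- baf$folded_baf[baf$sample_id == s]
    fb <- if (length(b) == 0) 0.5 else b[1]
    loh <- call_loh(fb)
    cl <- classify_tp53_status(nmut, cat_s, loh)
    data.frame(sample_id = s, status = cl$status, cnv_category = cat_s,
               log2fc = lfc, folded_baf = fb, has_mutation = nmut >= 1,
               has_loh = loh, evidence_rule = cl$evidence_rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
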