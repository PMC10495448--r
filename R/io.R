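# Readers and writers for the pipeline's plain-text tables (TSV + JSON),
# with schema validation that names the offending file, line and column.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.check <- function(ok, path, rows, what) {
  if (any(!ok))
    stop(sprintf("%s: %s at line(s) %s", path, what,
                 paste(utils::head(rows[!ok] + 1L, 5), collapse = ", ")))
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
}

#' Read a MAF-style mutation table
#'
#' Minimal columns: sample_id, gene, chrom, pos, ref, alt, consequence,
#' vaf.  VAF must be in [0, 1] and positions positive.
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                      "consequence", "vaf"), path)
  rows <- seq_len(nrow(df))
  .check(df$vaf >= 0 & df$vaf <= 1, path, rows, "VAF out of [0, 1]")
  .check(df$pos > 0, path, rows, "non-positive position")
  df
}

#' Read a SEG-style copy-number segment table
#' @param path TSV with sample_id, chrom, start, end, log2fc (1-based
#'   inclusive).
#' @return Validated data.frame.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "chrom", "start", "end", "log2fc"), path)
  rows <- seq_len(nrow(df))
  .check(df$start <= df$end, path, rows, "start > end")
  .check(is.finite(df$log2fc), path, rows, "non-finite log2fc")
  df
}

#' Read a folded B-allele-frequency table
#' @param path TSV with sample_id, folded_baf in [0, 0.5].
#' @return Validated data.frame.
#' @export
read_baf <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "folded_baf"), path)
  .check(df$folded_baf >= 0 & df$folded_baf <= 0.5, path,
         seq_len(nrow(df)), "folded BAF out of [0, 0.5]")
  df
}

#' Read a genes-x-samples expression matrix
#' @param path TSV, first column \code{gene}, remaining columns samples.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene") stop(path, ": first column must be 'gene'")
  if (anyDuplicated(df$gene)) stop(path, ": duplicated gene names")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (any(m < 0)) stop(path, ": negative expression values")
  m
}

#' Read a splicing event count table
#' @param path TSV with sample_id, event_id, event_class, intron_reads,
#'   junction_reads.
#' @return Validated data.frame.
#' @export
read_splicing <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "event_id", "event_class",
                      "intron_reads", "junction_reads"), path)
  rows <- seq_len(nrow(df))
  .check(df$intron_reads >= 0 & df$junction_reads >= 0, path, rows,
         "negative read count")
  df
}

#' Read a clinical table with ISO dates
#' @param path TSV; date columns parsed as Date.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "diagnosis_date", "progression_date",
                      "death_date", "last_followup_date",
                      "first_abnormality_date"), path)
  for (col in grep("_date$", names(df), value = TRUE))
    df[[col]] <- as.Date(df[[col]])
  df
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' TSV tables (mutations, segments, BAF, expression, normal expression,
#' splicing counts, transcript TPM, class map, clinical) plus a JSON
#' ground-truth file.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(bundle$mutations, p("mutations.tsv"))
  .write_tsv(bundle$segments, p("segments.tsv"))
  .write_tsv(bundle$baf, p("baf.tsv"))
  em <- data.frame(gene = rownames(bundle$expression),
                   bundle$expression, check.names = FALSE)
  .write_tsv(em, p("expression.tsv"))
  nm <- data.frame(gene = rownames(bundle$normal_expression),
                   bundle$normal_expression, check.names = FALSE)
  .write_tsv(nm, p("normal_expression.tsv"))
  .write_tsv(bundle$splicing, p("splicing.tsv"))
  tx <- data.frame(transcript_id = rownames(bundle$transcript_tpm),
                   bundle$transcript_tpm, check.names = FALSE)
  .write_tsv(tx, p("transcript_tpm.tsv"))
  .write_tsv(bundle$class_map, p("class_map.tsv"))
  cl <- bundle$clinical
  for (col in grep("_date$", names(cl), value = TRUE))
    cl[[col]] <- as.character(cl[[col]])
  .write_tsv(cl, p("clinical.tsv"))
  jsonlite::write_json(list(truth = bundle$truth,
                            normal_ids = bundle$normal_ids,
                            seed = bundle$config$seed),
                       p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort bundle written by \code{\link{write_bundle}}
#' @param dir Bundle directory.
#' @return List with the same table components as a \code{cohort_bundle}
#'   (without the generating config).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  tx <- .read_tsv(p("transcript_tpm.tsv"))
  txm <- as.matrix(tx[, -1, drop = FALSE])
  rownames(txm) <- tx$transcript_id
  structure(list(
    mutations = read_mutations(p("mutations.tsv")),
    segments = read_segments(p("segments.tsv")),
    baf = read_baf(p("baf.tsv")),
    expression = read_expression(p("expression.tsv")),
    normal_expression = read_expression(p("normal_expression.tsv")),
    splicing = read_splicing(p("splicing.tsv")),
    transcript_tpm = txm,
    class_map = .read_tsv(p("class_map.tsv")),
    clinical = read_clinical(p("clinical.tsv")),
    truth = gt$truth, normal_ids = gt$normal_ids,
    samples = gt$truth$sample_id), class = "cohort_bundle")
}
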