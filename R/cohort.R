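# Seeded synthetic-cohort generator.  Emulates the statistical structure of
# a myeloma cohort with known biallelic / monoallelic / wild-type TP53
# status: per-sample genomic tables, a TPM expression matrix with a planted
# biallelic signature, splicing count tables with mechanism-linked events,
# transcript-class TPM, a clinical table with group-differential survival,
# and the ground-truth labels that make every downstream stage testable.

#' Configuration of the synthetic cohort
#'
#' Defaults encode the cohort structure assumed throughout: class
#' prevalences 3.6\% biallelic / 9.8\% monoallelic (86.5\% wild-type), 42\%
#' cryptic biallelic samples hidden among the monoallelic ones, a 16-gene
#' signature with per-gene |log2 effect| drawn in [1, 3] (half up, half
#' down) on top of log-normal expression noise, binomial splicing counts
#' over a Poisson total depth, and exponential survival with
#' group-specific medians.
#'
#' @param n_samples Cohort size (>= 10).
#' @param prevalence_biallelic,prevalence_monoallelic Class prevalences
#'   (defaults 0.036 and 0.098); must sum to <= 1.
#' @param frac_cryptic_biallelic_among_mono Fraction of monoallelic samples
#'   that are truly (cryptically) biallelic (default 0.42).
#' @param n_signature_genes Number of planted signature genes (default 16).
#' @param n_background_genes Number of null background genes (default 500).
#' @param signature_log2_effect Signed per-gene log2 effects; NULL (default)
#'   draws magnitudes uniformly in [1, 3] with half the genes up and half
#'   down; a scalar is recycled.
#' @param expression_noise_sd Per-gene noise sd on the log2(TPM + 1) scale
#'   (default 0.5).
#' @param splicing_baseline_psi,splicing_planted_psi Cryptic-event PSI in
#'   unaffected vs mechanism-planted samples (defaults 0.05 and 0.60).
#' @param mean_depth Expected total reads per splicing event (default 200).
#' @param survival_median_days_by_group Named vector of median PFS days per
#'   true status (defaults biallelic 478, cryptic_biallelic 623,
#'   monoallelic 900, WT 1176).
#' @param censor_rate Fraction of samples subject to an independent uniform
#'   censoring time (default 0.3).
#' @param n_normals Number of normal plasma-cell control samples (default 5).
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @return List of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_samples = 634,
                          prevalence_biallelic = 0.036,
                          prevalence_monoallelic = 0.098,
                          frac_cryptic_biallelic_among_mono = 0.42,
                          n_signature_genes = 16,
                          n_background_genes = 500,
                          signature_log2_effect = NULL,
                          expression_noise_sd = 0.5,
                          splicing_baseline_psi = 0.05,
                          splicing_planted_psi = 0.60,
                          mean_depth = 200,
                          survival_median_days_by_group =
                            c(biallelic = 478, cryptic_biallelic = 623,
                              monoallelic = 900, WT = 1176),
                          censor_rate = 0.3,
                          n_normals = 5,
                          seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (prevalence_biallelic < 0 || prevalence_monoallelic < 0 ||
      prevalence_biallelic + prevalence_monoallelic > 1)
    stop("prevalences must be non-negative and sum to <= 1")
  fracs <- c(frac_cryptic_biallelic_among_mono, censor_rate,
             splicing_baseline_psi, splicing_planted_psi)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (any(survival_median_days_by_group <= 0))
    stop("survival medians must be positive")
  if (!is.null(signature_log2_effect)) {
    signature_log2_effect <- rep_len(signature_log2_effect,
                                     n_signature_genes)
  }
  structure(list(
    n_samples = n_samples,
    prevalence_biallelic = prevalence_biallelic,
    prevalence_monoallelic = prevalence_monoallelic,
    frac_cryptic_biallelic_among_mono = frac_cryptic_biallelic_among_mono,
    n_signature_genes = n_signature_genes,
    n_background_genes = n_background_genes,
    signature_log2_effect = signature_log2_effect,
    expression_noise_sd = expression_noise_sd,
    splicing_baseline_psi = splicing_baseline_psi,
    splicing_planted_psi = splicing_planted_psi,
    mean_depth = mean_depth,
    survival_median_days_by_group = survival_median_days_by_group,
    censor_rate = censor_rate,
    n_normals = n_normals,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Simulate intron/junction read counts for one splicing event
#'
#' The total read depth is Poisson(\code{mean_depth}) and the intron reads
#' are a binomial split with inclusion probability \code{psi_target}, so
#' the observed PSI has expectation \code{psi_target}.
#'
#' @param psi_target Target PSI in [0, 1] (vectorised).
#' @param mean_depth Expected total reads (> 0).
#' @return data.frame with \code{intron_reads} and \code{junction_reads}.
#' @export
simulate_splicing_counts <- function(psi_target, mean_depth) {
  if (any(psi_target < 0 | psi_target > 1)) stop("psi_target must be in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  n <- length(psi_target)
  total <- stats::rpois(n, mean_depth)
  intron <- stats::rbinom(n, total, psi_target)
  data.frame(intron_reads = intron, junction_reads = total - intron)
}

#' Simulate survival times for a group
#'
#' Event times are exponential with the given median (rate log(2)/median).
#' A fraction \code{censor_rate} of subjects independently receives a
#' uniform censoring time on [0, \code{censor_upper}]; the observed time is
#' the earlier of the two.
#'
#' @param n Number of subjects.
#' @param median_days Median event time in days (> 0).
#' @param censor_rate Fraction of subjects eligible for censoring.
#' @param censor_upper Upper bound of the uniform censoring window
#'   (default 2 * median_days).
#' @return data.frame with \code{time} (days) and \code{event} (1/0).
#' @export
simulate_survival_times <- function(n, median_days, censor_rate = 0,
                                    censor_upper = 2 * median_days) {
  if (median_days <= 0) stop("median_days must be positive")
  t_event <- stats::rexp(n, rate = log(2) / median_days)
  censored <- stats::runif(n) < censor_rate
  c_time <- stats::runif(n, 0, censor_upper)
  time <- ifelse(censored, pmin(t_event, c_time), t_event)
  event <- as.numeric(!censored | t_event <= c_time)
  data.frame(time = time, event = event)
}

#' Default TP53 transcript-to-isoform class map
#'
#' One synthetic transcript per isoform class: cryptic-exon form 0/1/2
#' (alpha/beta/gamma) crossed with the four N-terminal length classes.
#' @return data.frame: \code{transcript_id}, \code{cryptic_exon_form},
#'   \code{length_class}.
#' @export
default_class_map <- function() {
  lc <- c("TA", "d40", "d133", "d160")
  form <- 0:2
  grid <- expand.grid(length_class = lc, cryptic_exon_form = form,
                      stringsAsFactors = FALSE)
  ctype <- c("alpha", "beta", "gamma")[grid$cryptic_exon_form + 1L]
  data.frame(transcript_id = paste("TP53", grid$length_class, ctype,
                                   sep = "_"),
             cryptic_exon_form = grid$cryptic_exon_form,
             length_class = grid$length_class, stringsAsFactors = FALSE)
}

# Internal: per-status DNA mechanism pools
.biallelic_mechs <- c("deep_deletion", "mutation+deletion", "mutation+LOH")
.cryptic_mechs <- c("cryptic_exon+LOH", "cryptic_exon+deletion",
                    "low_expression+deletion", "retained_intron",
                    "splice_site_mutation")
.mono_rules <- c("mono_mutation", "mono_deletion", "mono_LOH")

#' Generate a synthetic cohort bundle
#'
#' Draws per-sample true status from the configured prevalences, plants a
#' transcriptomic mechanism in the cryptic biallelic samples, and emits
#' genomic tables consistent with the DNA-level component of the truth, an
#' expression matrix carrying the signature shift in all (known and
#' cryptic) biallelic samples, splicing counts, transcript-class TPM, and a
#' clinical table with group-differential survival.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List of class \code{"cohort_bundle"} with elements
#'   \code{config}, \code{samples}, \code{truth}, \code{mutations},
#'   \code{segments}, \code{baf}, \code{expression},
#'   \code{normal_expression}, \code{splicing}, \code{normal_ids},
#'   \code{transcript_tpm}, \code{class_map}, \code{clinical}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("MM_%04d", seq_len(n))
  normal_ids <- sprintf("BMPC_%d", seq_len(config$n_normals))

  ## ---- ground truth -------------------------------------------------
  p_b <- config$prevalence_biallelic
  p_m <- config$prevalence_monoallelic
  base_status <- sample(c("biallelic", "monoallelic", "WT"), n,
                        replace = TRUE, prob = c(p_b, p_m, 1 - p_b - p_m))
  cryptic <- base_status == "monoallelic" &
    stats::runif(n) < config$frac_cryptic_biallelic_among_mono
  true_status <- base_status
  true_status[cryptic] <- "cryptic_biallelic"

  mech <- rep("none", n)
  dna_rule <- rep("none", n)
  i_b <- which(true_status == "biallelic")
  mech[i_b] <- sample(.biallelic_mechs, length(i_b), replace = TRUE)
  dna_rule[i_b] <- mech[i_b]
  i_c <- which(true_status == "cryptic_biallelic")
  mech[i_c] <- sample(.cryptic_mechs, length(i_c), replace = TRUE)
  dna_rule[i_c] <- c("cryptic_exon+LOH" = "mono_LOH",
                     "cryptic_exon+deletion" = "mono_deletion",
                     "low_expression+deletion" = "mono_deletion",
                     "retained_intron" = "mono_deletion",
                     "splice_site_mutation" = "mono_mutation")[mech[i_c]]
  i_m <- which(true_status == "monoallelic")
  dna_rule[i_m] <- sample(.mono_rules, length(i_m), replace = TRUE)

  truth <- data.frame(sample_id = samples, true_status = true_status,
                      planted_mechanism = mech, dna_rule = dna_rule,
                      stringsAsFactors = FALSE)

  ## ---- genomic tables ----------------------------------------------
  gi <- tp53_interval()
  has_mut <- dna_rule %in% c("mutation+deletion", "mutation+LOH",
                             "mono_mutation")
  mut_conseq <- ifelse(mech == "splice_site_mutation", "splice_site",
                       sample(c("missense", "nonsense", "frameshift"), n,
                              replace = TRUE))
  vaf <- ifelse(mech == "splice_site_mutation",
                stats::runif(n, 0.3, 0.9), stats::runif(n, 0.3, 0.95))
  mi <- which(has_mut)
  mutations <- data.frame(
    sample_id = samples[mi], gene = rep("TP53", length(mi)),
    chrom = rep(gi$chrom, length(mi)),
    pos = sample(gi$start:gi$end, length(mi), replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), length(mi), replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), length(mi), replace = TRUE),
    consequence = mut_conseq[mi], vaf = round(vaf[mi], 3),
    stringsAsFactors = FALSE)
  # decoy non-TP53 mutations exercise the gene filter
  di <- which(stats::runif(n) < 0.05)
  if (length(di) > 0)
    mutations <- rbind(mutations, data.frame(
      sample_id = samples[di], gene = "NRAS", chrom = "chr1",
      pos = sample(114704469:114716894, length(di), replace = TRUE),
      ref = "G", alt = "T", consequence = "missense",
      vaf = round(stats::runif(length(di), 0.1, 0.6), 3),
      stringsAsFactors = FALSE))

  cnv_deletion <- dna_rule %in% c("mutation+deletion", "mono_deletion")
  tp53_log2fc <- ifelse(dna_rule == "deep_deletion",
                        stats::runif(n, -3.5, -2.1),
                 ifelse(cnv_deletion, stats::runif(n, -1.8, -0.3),
                        stats::runif(n, -0.1, 0.1)))
  segments <- rbind(
    data.frame(sample_id = samples, chrom = gi$chrom,
               start = 7500000L, end = 7800000L,
               log2fc = round(tp53_log2fc, 3), stringsAsFactors = FALSE),
    data.frame(sample_id = samples, chrom = "chr1",
               start = 1000000L, end = 2000000L,
               log2fc = round(stats::runif(n, -1, 1), 3),
               stringsAsFactors = FALSE))

  has_loh <- dna_rule %in% c("deep_deletion", "mutation+deletion",
                             "mutation+LOH", "mono_deletion", "mono_LOH")
  folded <- ifelse(has_loh, stats::runif(n, 0, 0.2),
                   stats::runif(n, 0.28, 0.5))
  baf <- data.frame(sample_id = samples, folded_baf = round(folded, 4),
                    stringsAsFactors = FALSE)

  ## ---- expression ---------------------------------------------------
  n_sig <- config$n_signature_genes
  n_bg <- config$n_background_genes
  sig_genes <- sprintf("SIG%02d", seq_len(n_sig))
  bg_genes <- sprintf("BG%03d", seq_len(n_bg))
  genes <- c(sig_genes, bg_genes, "TP53", "MED18")

  effects <- config$signature_log2_effect
  if (is.null(effects)) {
    sign <- rep(c(1, -1), length.out = n_sig)
    effects <- sign * stats::runif(n_sig, 1, 3)
  }
  affected <- true_status %in% c("biallelic", "cryptic_biallelic")

  baseline <- stats::runif(n_sig + n_bg, 2, 6)
  log_expr <- matrix(baseline, nrow = n_sig + n_bg, ncol = n,
                     dimnames = list(c(sig_genes, bg_genes), samples))
  log_expr[seq_len(n_sig), affected] <-
    log_expr[seq_len(n_sig), affected, drop = FALSE] + effects
  log_expr <- log_expr +
    matrix(stats::rnorm((n_sig + n_bg) * n, 0, config$expression_noise_sd),
           nrow = n_sig + n_bg)

  # TP53 gene expression: low in deep deletion and in the planted
  # low-expression mechanism, baseline 3.0 otherwise
  tp53_mu <- ifelse(mech == "low_expression+deletion", 0.7,
             ifelse(dna_rule == "deep_deletion", 0.6, 3.0))
  tp53_log <- tp53_mu + stats::rnorm(n, 0, 0.3)

  # per-sample cryptic-exon inclusion level (latent PSI target): planted in
  # cryptic-exon mechanism samples, jitter around baseline otherwise
  base_psi <- config$splicing_baseline_psi
  planted_psi <- config$splicing_planted_psi
  ce_planted <- mech %in% c("cryptic_exon+LOH", "cryptic_exon+deletion")
  psi_ce <- ifelse(ce_planted,
                   pmin(1, pmax(0, planted_psi + stats::runif(n, -0.05, 0.05))),
                   base_psi * stats::runif(n, 0, 2))

  # MED18-like splicing regulator: expression tracks cryptic-exon inclusion
  med18_log <- 3.0 + 4 * psi_ce + stats::rnorm(n, 0, 0.15)

  log_expr <- rbind(log_expr,
                    TP53 = tp53_log,
                    MED18 = med18_log)
  log_expr <- pmax(log_expr, 0)
  expression <- round(inv_log_transform(log_expr), 4)

  normal_log <- matrix(c(baseline, 3.0, 3.0 + 4 * base_psi),
                       nrow = n_sig + n_bg + 2, ncol = config$n_normals,
                       dimnames = list(genes, normal_ids))
  normal_log <- pmax(normal_log +
    matrix(stats::rnorm(length(normal_log), 0, config$expression_noise_sd),
           nrow = nrow(normal_log)), 0)
  normal_expression <- round(inv_log_transform(normal_log), 4)

  ## ---- splicing counts ---------------------------------------------
  ri_planted <- mech == "retained_intron"
  ss_planted <- mech == "splice_site_mutation"
  ri_base <- 0.01
  psi_ri <- ifelse(ri_planted,
                   pmin(1, pmax(0, planted_psi + stats::runif(n, -0.05, 0.05))),
                   ri_base * stats::runif(n, 0, 2))
  psi_ss <- ifelse(ss_planted, pmin(0.95, vaf * 0.8),
                   ri_base * stats::runif(n, 0, 2))

  events <- list(
    list(id = "TP53_cryptic_exon_9_10", class = "cryptic_exon",
         tumor = psi_ce, normal = base_psi),
    list(id = "TP53_RI_intron6_8", class = "retained_intron",
         tumor = psi_ri, normal = ri_base),
    list(id = "TP53_RI_intron9", class = "retained_intron",
         tumor = psi_ss, normal = ri_base))
  splicing <- do.call(rbind, lapply(events, function(e) {
    tum <- simulate_splicing_counts(e$tumor, config$mean_depth)
    nor <- simulate_splicing_counts(rep(e$normal, config$n_normals),
                                    config$mean_depth)
    data.frame(sample_id = c(samples, normal_ids), event_id = e$id,
               event_class = e$class,
               intron_reads = c(tum$intron_reads, nor$intron_reads),
               junction_reads = c(tum$junction_reads, nor$junction_reads),
               stringsAsFactors = FALSE)
  }))

  ## ---- transcript-class TPM ----------------------------------------
  cmap <- default_class_map()
  base_tpm <- stats::setNames(rep(0.2, nrow(cmap)), cmap$transcript_id)
  base_tpm["TP53_TA_alpha"] <- 6
  tx <- sapply(seq_len(n), function(i) {
    mu <- base_tpm
    if (ce_planted[i]) {
      mu["TP53_TA_alpha"] <- 2
      mu["TP53_TA_beta"] <- 2.5
      mu["TP53_TA_gamma"] <- 1.5
    }
    if (mech[i] == "low_expression+deletion") mu <- mu * 0.1
    mu * exp(stats::rnorm(length(mu), 0, 0.2))
  })
  dimnames(tx) <- list(cmap$transcript_id, samples)
  transcript_tpm <- round(tx, 4)

  ## ---- clinical -----------------------------------------------------
  medians <- config$survival_median_days_by_group
  missing_grp <- setdiff(unique(true_status), names(medians))
  if (length(missing_grp) > 0)
    stop("no survival median configured for group(s): ",
         paste(missing_grp, collapse = ", "))
  censor_upper <- 2 * max(medians)
  t_pfs <- stats::rexp(n, rate = log(2) / medians[true_status])
  t_extra <- stats::rexp(n, rate = log(2) / (1.5 * medians[true_status]))
  t_os <- t_pfs + t_extra
  censored <- stats::runif(n) < config$censor_rate
  c_time <- stats::runif(n, 1, censor_upper)

  day <- function(x) pmax(1, round(x))
  origin <- as.Date("2015-01-01")
  prog_day <- ifelse(censored & c_time < t_pfs, NA, day(t_pfs))
  death_day <- ifelse(censored & c_time < t_os, NA, day(t_os))
  fu_day <- ifelse(is.na(death_day), day(pmin(c_time, censor_upper)),
                   death_day)
  # follow-up never precedes an observed progression
  fu_day <- pmax(fu_day, ifelse(is.na(prog_day), 1, prog_day))
  clinical <- data.frame(
    sample_id = samples,
    diagnosis_date = origin,
    progression_date = origin + prog_day,
    death_date = origin + death_day,
    last_followup_date = origin + fu_day,
    first_abnormality_date = as.Date(ifelse(true_status == "WT", NA,
                                            as.character(origin))),
    group = true_status, stringsAsFactors = FALSE)

  structure(list(config = config, samples = samples, truth = truth,
                 mutations = mutations, segments = segments, baf = baf,
                 expression = expression,
                 normal_expression = normal_expression,
                 splicing = splicing, normal_ids = normal_ids,
                 transcript_tpm = transcript_tpm, class_map = cmap,
                 clinical = clinical),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$truth$true_status)
  cat(sprintf("synthetic cohort: %d samples (%s), %d genes, seed %d\n",
              length(x$samples),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              nrow(x$expression), x$config$seed))
  invisible(x)
}
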