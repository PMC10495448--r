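# Independent oracles and small fixture builders shared across tests.

# AUROC as the Mann-Whitney concordance probability, by explicit pairwise
# comparison (ties count 1/2).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# AUPRC by exhaustive threshold enumeration, recounting TP/FP from scratch
# at every unique score.
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    r <- tp / n_pos
    p <- tp / (tp + fp)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# Random scored instance with both classes present; tied scores arise from
# rounding.
random_instance <- function(n, round_digits = 1) {
  repeat {
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) == 2) break
  }
  list(scores = round(stats::runif(n), round_digits), labels = labels)
}

# Mann-Whitney U by direct pair counting (greater counts 1, tie 1/2).
oracle_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact two-sided Mann-Whitney p by enumeration over value assignments
# (independent of the rank-based route in the package).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  mu <- nx * length(y) / 2
  u_obs <- oracle_u(x, y)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hand-enumerated truth table for the TP53 status rules:
# mutation {0,1} x CNV category (5) x LOH {F,T} = 20 cases.
status_truth_table <- function() {
  tab <- expand.grid(mut = 0:1, cnv = cnv_categories(), loh = c(FALSE, TRUE),
                     stringsAsFactors = FALSE)
  expected <- function(mut, cnv, loh) {
    if (cnv == "deep_deletion") return(c("biallelic", "deep_deletion"))
    if (mut == 1 && cnv == "deletion") return(c("biallelic", "mutation+deletion"))
    if (mut == 1 && loh) return(c("biallelic", "mutation+LOH"))
    if (mut == 1) return(c("monoallelic", "mono_mutation"))
    if (cnv == "deletion") return(c("monoallelic", "mono_deletion"))
    if (loh) return(c("monoallelic", "mono_LOH"))
    c("WT", "none")
  }
  exp <- t(mapply(expected, tab$mut, tab$cnv, tab$loh))
  tab$status <- exp[, 1]
  tab$evidence_rule <- exp[, 2]
  tab
}

# Small well-separated two-class expression fixture for model tests.
toy_features <- function(n_pos = 15, n_neg = 60, n_genes = 6, shift = 2,
                         sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(stats::rnorm(n * n_genes, 3, sd), nrow = n,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("G%02d", seq_len(n_genes))))
  x[seq_len(n_pos), ] <- x[seq_len(n_pos), ] + shift
  list(x = x, y = rep(c(1L, 0L), c(n_pos, n_neg)))
}
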