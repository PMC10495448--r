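# Native survival statistics: endpoint derivation (PFS/OS/ARS),
# Kaplan-Meier product-limit estimation with median survival, the
# two-group log-rank test, and the Mann-Whitney U test with exact
# enumeration for small samples.

#' Derive survival endpoints from a clinical table
#'
#' PFS is the time from diagnosis to progression or death (whichever comes
#' first; censored at last follow-up); OS is the time from diagnosis to
#' death; ARS (after-relapse survival) is the time from the first
#' detection/prediction of the TP53 abnormality to death or censoring.
#' Samples without a first-abnormality date contribute no ARS record.
#'
#' @param clinical data.frame with columns \code{sample_id},
#'   \code{diagnosis_date}, \code{progression_date}, \code{death_date},
#'   \code{last_followup_date}, \code{first_abnormality_date} (Date or
#'   numeric day offsets; NA where the event did not occur) and optionally
#'   \code{group}.
#' @return data.frame of survival records: \code{sample_id},
#'   \code{endpoint} ("PFS", "OS", "ARS"), \code{time} (days, > 0),
#'   \code{event} (1 = event, 0 = censored), \code{group}.
#' @export
derive_endpoints <- function(clinical) {
  need <- c("sample_id", "diagnosis_date", "progression_date", "death_date",
            "last_followup_date", "first_abnormality_date")
  stopifnot(all(need %in% names(clinical)))
  grp <- if ("group" %in% names(clinical)) clinical$group
  else rep(NA_character_, nrow(clinical))
  num <- function(x) as.numeric(x)

  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    d0 <- num(clinical$diagnosis_date[i])
    prog <- num(clinical$progression_date[i])
    death <- num(clinical$death_date[i])
    fu <- num(clinical$last_followup_date[i])
    abn <- num(clinical$first_abnormality_date[i])
    s <- clinical$sample_id[i]

    pfs_evt_time <- suppressWarnings(min(prog, death, na.rm = TRUE))
    pfs <- if (is.finite(pfs_evt_time))
      c(time = pfs_evt_time - d0, event = 1)
    else c(time = fu - d0, event = 0)
    os <- if (!is.na(death)) c(time = death - d0, event = 1)
    else c(time = fu - d0, event = 0)
    out <- data.frame(sample_id = s, endpoint = c("PFS", "OS"),
                      time = c(pfs[["time"]], os[["time"]]),
                      event = c(pfs[["event"]], os[["event"]]),
                      group = grp[i], stringsAsFactors = FALSE)
    if (!is.na(abn)) {
      ars_end <- if (!is.na(death)) death else fu
      out <- rbind(out, data.frame(sample_id = s, endpoint = "ARS",
                                   time = ars_end - abn,
                                   event = as.numeric(!is.na(death)),
                                   group = grp[i], stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (any(out$time <= 0))
    stop("non-positive survival duration for sample(s): ",
         paste(unique(out$sample_id[out$time <= 0]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Events at tied times are processed before censorings at the same time
#' (standard convention).  The median is the smallest event time t with
#' S(t) <= 0.5, or "not reached" (NA) when S never drops to 0.5.
#'
#' @param time Positive times (days).
#' @param event 1 = event, 0 = censored.
#' @return Object of class \code{"km_estimate"}: data.frame \code{steps}
#'   (time, n_risk, n_event, surv), \code{median} (NA = not reached),
#'   \code{median_label}, \code{n}.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) > 0, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  surv <- 1
  steps <- data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <- surv * (1 - d / n_risk)
    steps <- rbind(steps, data.frame(time = t, n_risk = n_risk,
                                     n_event = d, surv = surv))
  }
  med <- if (nrow(steps) > 0 && any(steps$surv <= 0.5))
    steps$time[which(steps$surv <= 0.5)[1]] else NA_real_
  structure(list(steps = steps, median = med,
                 median_label = if (is.na(med)) "not reached"
                 else format(med), n = n),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d event times, median = %s\n",
              x$n, nrow(x$steps), x$median_label))
  invisible(x)
}

#' Evaluate a Kaplan-Meier step function S(t)
#' @param km A \code{km_estimate}.
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_surv <- function(km, t) {
  vapply(t, function(tt) {
    below <- km$steps$time <= tt
    if (!any(below)) 1 else km$steps$surv[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each event time the observed events in group A are compared with the
#' hypergeometric expectation given the risk sets; the statistic is the
#' squared standardised sum of (O - E), chi-square with 1 df.
#'
#' @param time_a,event_a Times and event flags for group A.
#' @param time_b,event_b Times and event flags for group B.
#' @return List of class \code{"logrank_result"}: \code{statistic},
#'   \code{p}, \code{observed} and \code{expected} (group A).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  if (sum(event) == 0) stop("no events in either group")
  ut <- sort(unique(time[event == 1]))
  o_sum <- e_sum <- v_sum <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d_tot <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    o_sum <- o_sum + d_a
    e_sum <- e_sum + d_tot * n_a / n_tot
    if (n_tot > 1)
      v_sum <- v_sum + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  stat <- if (v_sum > 0) (o_sum - e_sum)^2 / v_sum else 0
  structure(list(statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = o_sum, expected = e_sum, variance = v_sum),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with average ranks for ties.  The two-sided p-value is exact
#' (by complete enumeration of label assignments over the pooled ranks)
#' when min(n) <= 8 and n_x + n_y <= 16, and a normal approximation with
#' tie correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List: \code{U} (for \code{x}), \code{p}, \code{method}.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (min(nx, ny) <= 8 && nx + ny <= 16) {
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_corr)
    if (sigma2 == 0) { p <- 1 }
    else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method)
}
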