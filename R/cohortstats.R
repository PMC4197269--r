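#' Categorize expression against healthy donors
#'
#' A sample is called "up" when its expression exceeds the healthy-donor
#' mean by more than both thresholds at once (default: 2-fold and one order
#' of magnitude, so 10-fold is the effective cut), "down" when the healthy
#' mean exceeds it by the same margin, and "normal" otherwise. The two
#' clauses are applied conjunctively; both cuts are configurable.
#'
#' @param value Positive expression value(s) to classify.
#' @param healthy_values Non-empty positive vector of healthy-donor values.
#' @param fold_min Fold-change clause, default 2.
#' @param magnitude_min Order-of-magnitude clause, default 10.
#' @return Character vector in \{"up", "down", "normal"\}.
#' @export
classify_expression <- function(value, healthy_values, fold_min = 2,
                                magnitude_min = 10) {
  if (length(healthy_values) == 0L || any(healthy_values <= 0)) {
    stop("healthy_values must be non-empty and positive")
  }
  if (any(value <= 0)) stop("expression values must be positive")
  h <- mean(healthy_values)
  thr <- max(fold_min, magnitude_min)
  ifelse(value / h > thr, "up", ifelse(h / value > thr, "down", "normal"))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value by summation of hypergeometric probabilities not exceeding
#' that of the observed table (the standard two-sided convention).
#'
#' @param tab 2x2 matrix of non-negative counts (rows = groups, columns =
#'   outcome yes/no), or the count \code{a} with \code{b}, \code{c},
#'   \code{d} given separately.
#' @param b,c,d Remaining cells when \code{tab} is a single count.
#' @return List with \code{p_value} and the \code{table} tested.
#' @export
fisher_exact <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(tab)) {
    tab <- matrix(c(tab, b, c, d), nrow = 2L, byrow = TRUE)
  }
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  list(p_value = fisher.test(tab)$p.value, table = tab)
}

#' Mann-Whitney U test
#'
#' U computed by rank summation with average ranks for ties. The two-sided
#' p-value comes from exact enumeration of all assignments of the pooled
#' ranks when \code{min(n, m) <= exact_max} (valid with ties), and otherwise
#' from the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Enumeration cutoff on the smaller sample size.
#' @return List with \code{U} (for \code{x}; \code{U + U' = n * m}),
#'   \code{p_value} and \code{method}.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (min(n, m) <= exact_max) {
    # enumerate every assignment of n of the N pooled ranks to sample x
    idx <- combn(n + m, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    lo <- min(U, n * m - U); hi <- max(U, n * m - U)
    tol <- 1e-9
    p <- (sum(Us <= lo + tol) + sum(Us >= hi - tol)) / ncol(idx)
    list(U = U, p_value = min(1, p), method = "exact enumeration")
  } else {
    N <- n + m
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (n * m / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal approximation"))
    z <- (U - n * m / 2) / sqrt(sigma2)
    list(U = U, p_value = 2 * pnorm(-abs(z)), method = "normal approximation")
  }
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator under right censoring, via the survival package.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{surv}; \code{surv} starts at 1 and is
#'   non-increasing.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-sided log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance (1 df chi-square), via \code{survival::survdiff}.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List with \code{chisq}, \code{df} and \code{p_value}.
#' @export
logrank_test <- function(times, events, group) {
  if (length(unique(group)) < 2L) stop("need two non-empty groups")
  if (sum(events) == 0L) {
    stop("no events observed; the log-rank statistic is undefined")
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cumulative incidence of relapse with death as competing risk
#'
#' Aalen-Johansen estimator over the competing events relapse and death
#' without relapse, via the survival package's multi-state machinery. With
#' no competing deaths it reduces to one minus the Kaplan-Meier estimate of
#' relapse.
#'
#' @param times Follow-up times.
#' @param relapse_events Relapse indicators.
#' @param death_events Death-without-relapse indicators; mutually exclusive
#'   with \code{relapse_events} per sample.
#' @return data.frame with \code{time}, \code{cif_relapse},
#'   \code{cif_death}, \code{surv}; the three columns sum to 1 at every
#'   time point.
#' @export
relapse_incidence <- function(times, relapse_events, death_events) {
  if (any(relapse_events == 1 & death_events == 1)) {
    stop("relapse and death indicators must be mutually exclusive")
  }
  status <- factor(ifelse(relapse_events == 1, "relapse",
                          ifelse(death_events == 1, "death", "censor")),
                   levels = c("censor", "relapse", "death"))
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  states <- fit$states
  p <- fit$pstate
  data.frame(time = fit$time,
             cif_relapse = p[, match("relapse", states)],
             cif_death = p[, match("death", states)],
             surv = p[, match("(s0)", states)])
}
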