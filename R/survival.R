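#' Administrative censoring at a fixed horizon
#'
#' Truncates follow-up at `horizon` years: times beyond the horizon are set
#' to it and their events are censored. An event occurring exactly at the
#' horizon is kept as an event (recurrence within the window).
#'
#' @param time Non-negative follow-up times in years.
#' @param event 0/1 event indicators.
#' @param horizon Censoring horizon (> 0), default 10 years.
#' @return Data frame with censored `time` and `event`.
#' @export
censor_at <- function(time, event, horizon = 10) {
  stopifnot(horizon > 0, length(time) == length(event))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  event <- as.integer(event)
  over <- time > horizon
  data.frame(time = pmin(time, horizon),
             event = ifelse(over, 0L, event))
}

# comparable-pair indicator matrix: comp[i, j] is TRUE when subject i has an
# event strictly before subject j's time, so the pair is usable and i should
# carry the higher predictor.
.comparable_pairs <- function(time, event) {
  outer(time, time, "<") & (event == 1L)
}

# pair credit for a predictor on the comparable pairs: 1 concordant,
# 0.5 predictor tie, 0 discordant
.pair_credit <- function(predictor) {
  gt <- outer(predictor, predictor, ">")
  eq <- outer(predictor, predictor, "==")
  gt + 0.5 * eq
}

#' Concordance index
#'
#' Harrell's C over comparable pairs: a pair is comparable when one subject
#' has an event strictly before the other subject's observed time (tied
#' times are never comparable, which also excludes tied-time double-event
#' pairs). A comparable pair scores 1 when the event-earlier subject has the
#' higher predictor, 0.5 on a predictor tie, 0 otherwise;
#' `C = credit / comparable pairs`. Invariant to strictly monotone
#' transforms of the predictor.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param predictor Numeric risk score (higher = earlier event expected).
#' @return C in `[0, 1]`.
#' @export
concordance_index <- function(time, event, predictor) {
  stopifnot(length(time) == length(event), length(time) == length(predictor))
  event <- as.integer(event)
  comp <- .comparable_pairs(time, event)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs", call. = FALSE)
  sum(.pair_credit(predictor)[comp]) / n_comp
}

#' Compare two correlated concordance indices
#'
#' Paired test of `C_a - C_b` for two predictors evaluated on the same
#' subjects and outcomes (the Kang et al. style comparison for correlated
#' C-indices). The difference is a U-statistic; its variance is estimated by
#' the leave-one-subject-out jackknife over the shared comparable pairs,
#' giving `z = (C_a - C_b) / sd_jack` and a two-sided normal p-value.
#' Identical predictors give `p = 1`.
#'
#' @param time,event Shared survival outcomes.
#' @param pred_a,pred_b Two risk scores on the same subjects.
#' @return `attnmil_test` list: `statistic` (z), `p_value`, `estimate`
#'   (`C_a - C_b`), `c_a`, `c_b`, `n`.
#' @export
compare_correlated_cindex <- function(time, event, pred_a, pred_b) {
  n <- length(time)
  stopifnot(length(event) == n, length(pred_a) == n, length(pred_b) == n)
  event <- as.integer(event)
  comp <- .comparable_pairs(time, event)
  D <- sum(comp)
  if (D == 0) stop("no comparable pairs", call. = FALSE)
  cred_a <- .pair_credit(pred_a) * comp
  cred_b <- .pair_credit(pred_b) * comp
  Ka <- sum(cred_a); Kb <- sum(cred_b)
  delta <- (Ka - Kb) / D
  # leave-one-out: remove every pair subject i participates in
  d_i <- rowSums(comp) + colSums(comp)
  ka_i <- rowSums(cred_a) + colSums(cred_a)
  kb_i <- rowSums(cred_b) + colSums(cred_b)
  D_i <- D - d_i
  delta_loo <- ifelse(D_i > 0, ((Ka - ka_i) - (Kb - kb_i)) / D_i, delta)
  var_jack <- (n - 1) / n * sum((delta_loo - mean(delta_loo))^2)
  if (var_jack <= 0) {
    if (abs(delta) < 1e-12) {
      z <- 0; p <- 1
    } else {
      warning("zero jackknife variance with nonzero C difference",
              call. = FALSE)
      z <- sign(delta) * Inf; p <- 0
    }
  } else {
    z <- delta / sqrt(var_jack)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, estimate = delta,
                 c_a = Ka / D, c_b = Kb / D, n = n,
                 method = "paired comparison of correlated C-indices (jackknife)"),
            class = "attnmil_test")
}

#' Univariable Cox proportional hazards fit
#'
#' Maximizes the Cox partial likelihood with Breslow handling of tied event
#' times by Newton-Raphson (start `beta = 0`, convergence when the score
#' falls below `1e-8`, at most 50 iterations), for a single continuous or
#' binary predictor. Reports the Wald test `z = beta / se` with a two-sided
#' normal p-value. A monotone partial likelihood (perfect separation) is
#' flagged as non-convergence rather than returning a spurious estimate.
#'
#' @param time,event Follow-up times and 0/1 event indicators (at least one
#'   event required).
#' @param predictor Numeric predictor; must not be constant.
#' @return Object of class `cox_fit`: `coef`, `hr`, `se`, `z`, `p_value`,
#'   `converged`, `iter`, `n`, `n_events`.
#' @export
cox_univariable <- function(time, event, predictor) {
  n <- length(time)
  stopifnot(length(event) == n, length(predictor) == n)
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events", call. = FALSE)
  if (stats::sd(predictor) == 0) stop("constant predictor", call. = FALSE)
  x <- as.numeric(predictor)
  ev_times <- sort(unique(time[event == 1L]))
  # per event time: number of events, sum of x over events, risk-set mask
  beta <- 0; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    theta <- exp(beta * x)
    U <- 0; I <- 0
    for (tk in ev_times) {
      ev <- event == 1L & time == tk
      at_risk <- time >= tk
      d <- sum(ev)
      s0 <- sum(theta[at_risk])
      s1 <- sum(theta[at_risk] * x[at_risk])
      s2 <- sum(theta[at_risk] * x[at_risk]^2)
      U <- U + sum(x[ev]) - d * s1 / s0
      I <- I + d * (s2 / s0 - (s1 / s0)^2)
    }
    if (!is.finite(U) || !is.finite(I) || I <= 0) break
    if (abs(U) < 1e-8) { converged <- TRUE; break }
    beta <- beta + U / I
    if (abs(beta) > 15) break            # monotone likelihood
    if (iter >= 50L) break
  }
  se <- if (is.finite(I) && I > 0) 1 / sqrt(I) else NA_real_
  z <- beta / se
  if (!converged) {
    warning("Cox Newton-Raphson did not converge (possible perfect separation)",
            call. = FALSE)
  }
  structure(list(coef = beta, hr = exp(beta), se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 converged = converged, iter = iter,
                 n = n, n_events = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "univariable Cox (Breslow ties): coef = %.4g (HR %.4g), se = %.4g, z = %.3g, p = %.3g\n",
    x$coef, x$hr, x$se, x$z, x$p_value))
  if (!x$converged) cat("  [did not converge]\n")
  invisible(x)
}

#' Log-rank test
#'
#' Standard log-rank chi-square comparing survival between groups (O - E
#' summed over event times), via `survival::survdiff`; two-sided p-value on
#' `#groups - 1` degrees of freedom. Invariant to group relabelling.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group labels; at least two non-empty groups.
#' @return `attnmil_test` list: `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  n <- length(time)
  stopifnot(length(event) == n, length(group) == n)
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  sd_ <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- nlevels(group) - 1L
  structure(list(statistic = sd_$chisq, df = df,
                 p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 estimate = NA_real_,
                 method = "log-rank test"),
            class = "attnmil_test")
}

#' Cumulative recurrence curves
#'
#' One minus the Kaplan-Meier estimate per group, as step functions.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Optional group labels (single pooled curve when omitted).
#' @return Named list of data frames `(time, cuminc)`, each starting at
#'   `(0, 0)` and stepping at the observed event times.
#' @export
cumulative_recurrence <- function(time, event, group = NULL) {
  n <- length(time)
  stopifnot(length(event) == n)
  if (is.null(group)) group <- rep("all", n)
  group <- factor(group)
  out <- lapply(levels(group), function(g) {
    ix <- group == g
    sf <- survival::survfit(
      survival::Surv(time[ix], as.integer(event[ix])) ~ 1)
    data.frame(time = c(0, sf$time), cuminc = c(0, 1 - sf$surv))
  })
  stats::setNames(out, levels(group))
}
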