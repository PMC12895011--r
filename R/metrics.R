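#' ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a random positive scores above a random negative, with
#' half credit for ties: computed from midranks, which is exactly the mean
#' over positive-negative pairs of `1[s+ > s-] + 0.5 * 1[s+ == s-]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels (or logical); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' DeLong test for two correlated ROC AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects,
#' using DeLong's structural-component covariance of the paired AUCs:
#' `z = (AUC_a - AUC_b) / sd(AUC_a - AUC_b)`, two-sided normal p-value.
#' Degenerate cases are resolved by the difference itself: zero variance
#' with a zero AUC difference gives `p = 1`; zero variance with a nonzero
#' difference gives `p = 0` with a warning (pathological fixtures only).
#'
#' @param labels 0/1 labels shared by both scores.
#' @param scores_a,scores_b Two score vectors on the same subjects.
#' @return List of class `attnmil_test`: `statistic` (z), `p_value`,
#'   `estimate` (AUC difference), `auc_a`, `auc_b`, `method`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  est <- auc_a - auc_b
  roc_a <- pROC::roc(labels, scores_a, direction = "<", quiet = TRUE,
                     levels = c(0, 1))
  roc_b <- pROC::roc(labels, scores_b, direction = "<", quiet = TRUE,
                     levels = c(0, 1))
  z <- NA_real_; p <- NA_real_
  tt <- tryCatch(pROC::roc.test(roc_a, roc_b, method = "delong",
                                paired = TRUE),
                 error = function(e) NULL)
  if (!is.null(tt) && is.finite(tt$statistic) && is.finite(tt$p.value)) {
    z <- unname(tt$statistic)
    p <- tt$p.value
  } else if (abs(est) < 1e-12) {
    z <- 0; p <- 1
  } else {
    warning("zero DeLong variance with nonzero AUC difference", call. = FALSE)
    z <- sign(est) * Inf; p <- 0
  }
  structure(list(statistic = z, p_value = p, estimate = est,
                 auc_a = auc_a, auc_b = auc_b,
                 method = "DeLong test for two correlated ROC curves"),
            class = "attnmil_test")
}

#' @export
print.attnmil_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g, estimate = %.4g\n",
              x$statistic, x$p_value, x$estimate))
  invisible(x)
}

#' Pearson correlation with input validation
#'
#' @param x,y Numeric vectors, `n >= 3`, each with nonzero variance.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Meng's z-test for comparing two dependent correlations
#'
#' Tests whether two predictors correlate equally with a common criterion
#' (Meng, Rosenthal & Rubin). Inputs are the two criterion correlations
#' `r_a`, `r_b` and the predictor-predictor correlation `r_ab`, all from the
#' same `n` subjects. Using Fisher transforms `z_a`, `z_b`, the statistic is
#' `z = (z_a - z_b) * sqrt((n - 3) / (2 * (1 - r_ab) * h))` with
#' `rbar2 = (r_a^2 + r_b^2) / 2`, `f = min(1, (1 - r_ab) / (2 * (1 - rbar2)))`
#' and `h = (1 - f * rbar2) / (1 - rbar2)`; two-sided normal p-value.
#' Antisymmetric in `r_a`, `r_b`.
#'
#' @param r_a,r_b Correlations of predictors a and b with the criterion, in
#'   `(-1, 1)`.
#' @param r_ab Correlation between the two predictors.
#' @param n Number of subjects (> 3).
#' @return `attnmil_test` list: `statistic` (z), `p_value`, `estimate`
#'   (`r_a - r_b`).
#' @export
meng_z_test <- function(r_a, r_b, r_ab, n) {
  stopifnot(n > 3)
  if (any(abs(c(r_a, r_b)) >= 1)) {
    stop("correlations of magnitude 1 cannot be Fisher-transformed",
         call. = FALSE)
  }
  stopifnot(abs(r_ab) <= 1)
  z_a <- atanh(r_a); z_b <- atanh(r_b)
  rbar2 <- (r_a^2 + r_b^2) / 2
  f <- min(1, (1 - r_ab) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z_a - z_b) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  structure(list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                 estimate = r_a - r_b,
                 method = "Meng's z-test for dependent correlations"),
            class = "attnmil_test")
}

#' @rdname meng_z_test
#' @param criterion,pred_a,pred_b Raw vectors on the same subjects; the
#'   three correlations are computed from the same rows and passed to
#'   [meng_z_test()].
#' @export
meng_z_from_data <- function(criterion, pred_a, pred_b) {
  stopifnot(length(criterion) == length(pred_a),
            length(criterion) == length(pred_b))
  meng_z_test(pearson_r(pred_a, criterion),
              pearson_r(pred_b, criterion),
              pearson_r(pred_a, pred_b),
              length(criterion))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone, order-preserving,
#' adjusted >= raw). Thin validated wrapper around `p.adjust`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Optimal classification threshold by Youden's J
#'
#' Scans every unique observed score as a candidate threshold, classifying
#' `score >= t` as positive, and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`. Ties in J are broken toward the
#' smallest threshold (deterministic, favours sensitivity). In the
#' cross-validation workflow the threshold is selected on the pooled
#' validation-set predictions and then frozen for test predictions.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return The selected threshold (one of the observed scores).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  cand <- sort(unique(scores))
  # J * n_pos * n_neg = TP * n_neg + TN * n_pos - n_pos * n_neg is integer
  # valued, so maximizing it in integer arithmetic avoids float tie noise
  crit <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1L) * n_neg + sum(!pred & labels == 0L) * n_pos
  }, numeric(1))
  cand[which.max(crit)]  # which.max takes the first (smallest) maximizer
}
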