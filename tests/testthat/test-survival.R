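test_that("administrative censoring truncates at the horizon", {
  out <- censor_at(c(12, 10, 3), c(1, 1, 0), horizon = 10)
  expect_equal(out$time, c(10, 10, 3))
  # an event exactly at the horizon is kept; beyond it, censored
  expect_equal(out$event, c(0L, 1L, 0L))
  expect_error(censor_at(c(-1, 2), c(1, 0)), "non-negative")
})

test_that("concordance follows the comparable-pair definition", {
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 3, 1)), 2.5 / 3)
  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("concordance equals the brute-force oracle under censoring", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    time <- round(rexp(n, 0.2), 2)
    event <- rbinom(n, 1, 0.6)
    pred <- sample(1:5, n, replace = TRUE)   # ties likely
    if (sum(attnmil:::.comparable_pairs(time, event)) == 0) next
    expect_identical(concordance_index(time, event, pred),
                     oracle_cindex(time, event, pred))
  }
})

test_that("concordance invariants hold", {
  set.seed(9)
  time <- rexp(40); event <- rbinom(40, 1, 0.5); pred <- rnorm(40)
  c0 <- concordance_index(time, event, pred)
  # strictly monotone transform leaves C unchanged
  expect_equal(concordance_index(time, event, exp(pred)), c0)
  # negation flips it when no predictor ties exist
  expect_equal(concordance_index(time, event, -pred), 1 - c0)
  # tie-free fixture agrees with the field-standard implementation
  expect_equal(c0, unname(survival::concordance(
    survival::Surv(time, event) ~ pred, reverse = TRUE)$concordance))
})

test_that("correlated C-index comparison is calibrated at equality", {
  set.seed(10)
  time <- rexp(50); event <- rbinom(50, 1, 0.7); pred <- rnorm(50)
  same <- compare_correlated_cindex(time, event, pred, pred)
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry of the difference
  b <- rnorm(50)
  r1 <- compare_correlated_cindex(time, event, pred, b)
  r2 <- compare_correlated_cindex(time, event, b, pred)
  expect_equal(r1$estimate, -r2$estimate)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("correlated C-index p-value tracks a paired-bootstrap oracle", {
  set.seed(12)
  n <- 60
  time <- rexp(n, 0.3); event <- rbinom(n, 1, 0.7)
  risk <- rnorm(n)
  a <- risk + rnorm(n); b <- rnorm(n)
  res <- compare_correlated_cindex(time, event, a, b)
  # bootstrap the difference distribution; two-sided p from the normal
  # approximation to the bootstrap spread
  boot <- replicate(2000, {
    ix <- sample.int(n, replace = TRUE)
    tryCatch(concordance_index(time[ix], event[ix], a[ix]) -
               concordance_index(time[ix], event[ix], b[ix]),
             error = function(e) NA_real_)
  })
  boot <- boot[!is.na(boot)]
  p_boot <- 2 * pnorm(-abs(res$estimate) / sd(boot))
  expect_equal(res$p_value, p_boot, tolerance = 0.1)
})

test_that("univariable Cox matches a 1-D likelihood-scan oracle", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_univariable(time, event, x)
  # independent oracle: golden-section maximization of the explicit
  # Breslow partial log-likelihood
  pll <- function(b) {
    sum(vapply(which(event == 1), function(i) {
      at_risk <- time >= time[i]
      b * x[i] - log(sum(exp(b * x[at_risk])))
    }, numeric(1)))
  }
  opt <- optimize(pll, c(-10, 10), maximum = TRUE)
  expect_equal(fit$coef, opt$maximum, tolerance = 1e-4)
  # and the field-standard fit agrees
  cph <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(fit$coef, unname(coef(cph)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(unname(vcov(cph)[1, 1])), tolerance = 1e-6)
})

test_that("Cox estimates agree with coxph on random censored fixtures", {
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    x <- rnorm(n)
    time <- rexp(n, exp(0.5 * x) * 0.3)
    cen <- censor_at(time, rep(1, n), horizon = quantile(time, 0.8))
    fit <- cox_univariable(cen$time, cen$event, x)
    cph <- survival::coxph(survival::Surv(cen$time, cen$event) ~ x,
                           ties = "breslow")
    expect_equal(fit$coef, unname(coef(cph)), tolerance = 1e-6)
    expect_equal(fit$p_value,
                 summary(cph)$coefficients[1, "Pr(>|z|)"], tolerance = 1e-6)
  }
})

test_that("Cox coefficient negates with the predictor and rejects degenerates", {
  set.seed(14)
  x <- rnorm(30)
  time <- rexp(30, exp(0.8 * x))
  event <- rbinom(30, 1, 0.8)
  f1 <- cox_univariable(time, event, x)
  f2 <- cox_univariable(time, event, -x)
  expect_equal(f1$coef, -f2$coef, tolerance = 1e-8)
  expect_error(cox_univariable(time, event, rep(1, 30)), "constant")
  expect_error(cox_univariable(time, rep(0, 30), x), "no events")
})

test_that("log-rank matches the hand O/E oracle and label swaps", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-10)
  swap <- logrank_test(time, event, rev(group))
  expect_equal(res$statistic, swap$statistic)
  # duplicated data in two identical groups: no difference
  same <- logrank_test(rep(time, 2), rep(event, 2), rep(c("A", "B"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
  expect_error(logrank_test(time, event, rep("A", 4)), "two non-empty")
})

test_that("log-rank oracle agreement holds on random censored fixtures", {
  set.seed(15)
  for (i in 1:20) {
    n <- 40
    g <- rep(c("A", "B"), each = n / 2)
    time <- round(rexp(n, ifelse(g == "A", 0.3, 0.5)), 1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event[g == "A"]) == 0 || sum(event[g == "B"]) == 0) next
    expect_equal(logrank_test(time, event, g)$statistic,
                 oracle_logrank_chisq(time, event, g), tolerance = 1e-8)
  }
})

test_that("cumulative recurrence follows the product-limit estimate", {
  # hand table: times 1, 2, 2, 3, 5; events 1, 1, 0, 1, 0
  # S(1) = 4/5; S(2) = 4/5 * 3/4 = 3/5; S(3) = 3/5 * 1/2 = 3/10
  out <- cumulative_recurrence(c(1, 2, 2, 3, 5), c(1, 1, 0, 1, 0))$all
  at <- function(t) out$cuminc[max(which(out$time <= t))]
  expect_equal(at(1), 1 - 4 / 5)
  expect_equal(at(2.5), 1 - 3 / 5)
  expect_equal(at(4), 1 - 3 / 10)
  expect_equal(out$cuminc[1], 0)  # starts at zero
  # no events: flat zero
  flat <- cumulative_recurrence(c(1, 2, 3), c(0, 0, 0))$all
  expect_true(all(flat$cuminc == 0))
  # single event among n with no prior censoring: jump of 1/n
  one <- cumulative_recurrence(c(1, 2, 3, 4), c(1, 0, 0, 0))$all
  expect_equal(max(one$cuminc), 1 / 4)
})
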