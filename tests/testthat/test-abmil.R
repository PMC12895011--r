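test_that("a single-patch bag gets all the attention", {
  set.seed(1)
  p <- attnmil:::.abmil_init(4, 8, 6, 2)
  fw <- attnmil:::.abmil_forward(p, matrix(rnorm(4), 1, 4))
  expect_equal(fw$attention, 1)
})

test_that("forward pass matches a hand evaluation of the formula chain", {
  # d = L = D = 1, all weights 1, biases 0, features [1], [2]
  p <- list(W1 = matrix(1, 1, 1), b1 = 0, V = matrix(1, 1, 1), bV = 0,
            U = matrix(1, 1, 1), bU = 0, w = 1, bw = 0,
            W2 = matrix(1, 1, 1), b2 = 0)
  fw <- attnmil:::.abmil_forward(p, matrix(c(1, 2), 2, 1))
  # independent scalar evaluation
  h <- c(1, 2)                                 # relu(1 * x)
  a <- tanh(h) * (1 / (1 + exp(-h)))           # gated attention scores
  alpha <- exp(a) / sum(exp(a))
  expect_equal(fw$attention, alpha)
  expect_equal(fw$out, sum(alpha * h))
})

test_that("attention normalizes and permuting the bag permutes it", {
  set.seed(2)
  p <- attnmil:::.abmil_init(5, 16, 8, 2)
  X <- matrix(rnorm(12 * 5), 12, 5)
  fw <- attnmil:::.abmil_forward(p, X)
  expect_equal(sum(fw$attention), 1, tolerance = 1e-6)
  perm <- sample(12)
  fw2 <- attnmil:::.abmil_forward(p, X[perm, ])
  expect_equal(fw2$attention, fw$attention[perm])
  expect_equal(fw2$out, fw$out)
})

test_that("analytic gradients match finite differences for both heads", {
  set.seed(4)
  for (task in c("classification", "regression")) {
    K <- if (task == "classification") 2L else 1L
    y <- if (task == "classification") 1L else 0.7
    p <- attnmil:::.abmil_init(3, 4, 5, K)
    X <- matrix(rnorm(6 * 3), 6, 3)
    fw <- attnmil:::.abmil_forward(p, X, cache = TRUE)
    ls <- attnmil:::.abmil_loss(fw$out, y, task)
    gr <- attnmil:::.abmil_backward(p, fw$cache, ls$dout)
    eps <- 1e-6
    for (nm in names(p)) {
      for (i in seq_len(min(4, length(p[[nm]])))) {
        p2 <- p
        p2[[nm]][i] <- p2[[nm]][i] + eps
        l1 <- attnmil:::.abmil_loss(attnmil:::.abmil_forward(p2, X)$out, y, task)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        l2 <- attnmil:::.abmil_loss(attnmil:::.abmil_forward(p2, X)$out, y, task)$loss
        expect_equal(gr[[nm]][i], (l1 - l2) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("evaluation-mode prediction is deterministic and shape-checked", {
  co <- simulate_cohort(n_participants = 20, d = 8, signal_strength = 0.3,
                        seed = 6)
  y <- binarize_rorp_group(co$clinical$rorp_group)
  fit <- abmil(co$bags, y, "classification", config = quick_cfg(), seed = 1)
  p1 <- predict(fit, co$bags)
  p2 <- predict(fit, co$bags)
  expect_identical(p1, p2)
  pm <- predict(fit, co$bags, type = "prob")
  expect_equal(unname(rowSums(pm)), rep(1, 20), tolerance = 1e-12)
  al <- predict(fit, co$bags, type = "attention")
  expect_true(all(abs(vapply(al, sum, numeric(1)) - 1) < 1e-6))
  expect_error(predict(fit, matrix(rnorm(10), 2, 5)), "expects")
})

test_that("refitting with one seed reproduces the model exactly", {
  co <- simulate_cohort(n_participants = 15, d = 6, seed = 2)
  y <- co$clinical$rorp_score
  f1 <- abmil(co$bags, y, "regression", config = quick_cfg(), seed = 9)
  f2 <- abmil(co$bags, y, "regression", config = quick_cfg(), seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})

test_that("training on permuted labels yields chance-level discrimination", {
  co <- generate_null_cohort(n_participants = 60, d = 8,
                             signal_strength = 0.3, seed = 31)
  cv <- crossval_abmil(co, "classification", k = 5, config = quick_cfg(),
                       seed = 3)
  auc <- roc_auc(cv$predictions$prob_high, cv$predictions$label)
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("fold assignment is stratified, balanced and leakage-free", {
  co <- simulate_cohort(n_participants = 200, d = 2, patches_range = c(2, 3),
                        seed = 12)
  folds <- make_folds(co$clinical$participant_id, co$clinical$rorp_group,
                      k = 10, seed = 4)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  # per-fold risk-group proportions within 10 points of the cohort's
  grp <- co$clinical$rorp_group[match(names(folds),
                                      co$clinical$participant_id)]
  overall <- prop.table(table(grp))
  for (f in 1:10) {
    pf <- prop.table(table(grp[folds == f]))
    expect_true(all(abs(pf - overall[names(pf)]) <= 0.10))
  }
  expect_error(make_folds(paste0("P", 1:5), rep("a", 5), k = 10), "folds")
})

test_that("cross-validation partitions slides and never leaks participants", {
  co <- simulate_cohort(n_participants = 30, slides_per_participant = 2,
                        d = 6, signal_strength = 0.3, seed = 14)
  cv <- crossval_abmil(co, "classification", k = 5, config = quick_cfg(),
                       seed = 5)
  # every slide exactly one out-of-fold test prediction
  expect_setequal(cv$predictions$slide_id, co$clinical$slide_id)
  expect_false(anyDuplicated(cv$predictions$slide_id) > 0)
  # a participant's slides share one role per iteration: test participants
  # of fold i never appear in that iteration's validation set
  for (i in 1:5) {
    test_pids <- cv$predictions$participant_id[cv$predictions$fold == i]
    val_pids <- cv$val_predictions$participant_id[cv$val_predictions$fold == i]
    expect_length(intersect(test_pids, val_pids), 0)
  }
})

test_that("ensembling averages probabilities and ignores model order", {
  co <- simulate_cohort(n_participants = 12, d = 6, seed = 22)
  y <- binarize_rorp_group(co$clinical$rorp_group)
  f1 <- abmil(co$bags, y, "classification", config = quick_cfg(), seed = 1)
  f2 <- abmil(co$bags, y, "classification", config = quick_cfg(), seed = 2)
  # identical models ensemble to the single-model prediction
  same <- ensemble_predict(co$bags, list(f1, f1, f1))
  expect_equal(same$prob_high, predict(f1, co$bags))
  # two models average arithmetically and commute
  both <- ensemble_predict(co$bags, list(f1, f2))
  expect_equal(both$prob_high,
               (predict(f1, co$bags) + predict(f2, co$bags)) / 2)
  expect_equal(ensemble_predict(co$bags, list(f2, f1))$prob_high,
               both$prob_high)
  # heterogeneous shapes are rejected
  f3 <- abmil(co$bags, y, "classification",
              config = abmil_config(embed_dim = 8, attention_dim = 4,
                                    max_epochs = 2), seed = 1)
  expect_error(ensemble_predict(co$bags, list(f1, f3)), "heterogeneous")
})

test_that("eligibility restriction filters rows and warns when empty", {
  tab <- data.frame(slide_id = paste0("S", 1:10),
                    er_her2_eligible = rep(c(TRUE, FALSE), c(6, 4)),
                    score = rnorm(10))
  expect_equal(nrow(restrict_eligible(tab)), 6)
  expect_equal(restrict_eligible(tab), restrict_eligible(restrict_eligible(tab)))
  none <- tab; none$er_her2_eligible <- FALSE
  expect_warning(restrict_eligible(none), "no eligible")
})
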