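test_that("bag surgery preserves order and the original bag", {
  bag <- tiny_bag(matrix(1:20, 5, 4))
  cut <- remove_patches(bag, c(1, 5))
  expect_equal(n_patches(cut), 3)
  expect_equal(cut$features, bag$features[2:4, ])
  expect_equal(n_patches(bag), 5)                 # original untouched
  # remove(complement of S) == keep_only(S)
  expect_equal(remove_patches(bag, c(2, 4))$features,
               keep_only(bag, c(1, 3, 5))$features)
  # keeping everything is the identity on features
  expect_equal(keep_only(bag, 1:5)$features, bag$features)
  expect_error(remove_patches(bag, 1:5), "empty")
  expect_error(keep_only(bag, integer(0)), "empty")
  expect_error(remove_patches(bag, 9), "range")
  # removing disjoint sets sequentially equals removing the union
  s <- c(1, 2); t <- c(4)
  once <- remove_patches(bag, union(s, t))
  step1 <- remove_patches(bag, s)                 # rows 3, 4, 5 remain
  twice <- remove_patches(step1, match(t, setdiff(1:5, s)))
  expect_equal(once$features, twice$features)
  expect_equal(once$coords, twice$coords)
})

test_that("removing a mask and keeping its complement give the same bag", {
  bag <- tiny_bag(matrix(rnorm(24), 6, 4))
  mask <- c(2, 5)
  comp <- setdiff(1:6, mask)
  expect_equal(keep_only(bag, comp)$features,
               remove_patches(bag, mask)$features)
})

test_that("inserted patches append and extend the synthetic grid", {
  bag <- tiny_bag(matrix(rnorm(12), 3, 4))
  add <- matrix(rnorm(8), 2, 4)
  big <- insert_patches(bag, add)
  expect_equal(n_patches(big), 5)
  expect_equal(big$features[4:5, ], add)
  expect_false(anyDuplicated(big$coords) > 0)
  expect_gt(big$geometry$height_px, bag$geometry$height_px)
  expect_error(insert_patches(bag, matrix(1, 1, 3)), "dimension")
})

test_that("paired Cohen's d matches hand computation and its invariances", {
  expect_equal(cohens_d_paired(c(-1, -2, 0)), -1)     # mean -1, sd 1
  expect_equal(cohens_d_paired(c(1, 3, 2, 4) * 10),
               cohens_d_paired(c(1, 3, 2, 4)))        # scale invariant
  expect_warning(d <- cohens_d_paired(c(2, 2, 2)), "undefined")
  expect_true(is.na(d))
})

test_that("necessity and sufficiency tests use inclusion and pair bags", {
  # stub model: mean of feature column 1, mapped to (0, 1)
  mod <- function(bag) plogis(mean(bag$features[, 1]))
  bags <- list(); masks <- list()
  set.seed(20)
  for (i in 1:8) {
    x <- matrix(rnorm(10 * 4, sd = 0.3), 10, 4)
    sig <- sample(10, 4)
    x[sig, 1] <- x[sig, 1] + 3                       # planted high signal
    sid <- paste0("S", i)
    bags[[sid]] <- tiny_bag(x, slide_id = sid)
    masks[[sid]] <- region_mask(sid, patch_indices = sig)
  }
  nec <- necessity_test(mod, bags, masks)
  expect_equal(nec$n, 8)                             # all predicted > 0.5
  expect_lt(nec$mean_delta, 0)                       # removal hurts
  expect_lt(nec$cohens_d, 0)
  expect_lt(nec$p_value, 0.05)
  suf <- sufficiency_test(mod, bags, masks)
  expect_gte(suf$mean_delta, 0)                      # signal alone suffices
  # mask == complement identity: keep(mask) equals remove(complement)
  comp_masks <- lapply(masks, function(m) {
    region_mask(m$slide_id, patch_indices = setdiff(1:10, m$patch_indices))
  })
  nec2 <- necessity_test(mod, bags, comp_masks)
  expect_equal(suf$slides$perturbed, nec2$slides$perturbed)
})

test_that("degenerate masks are excluded or flagged", {
  mod <- function(bag) 0.9
  bags <- list(A = tiny_bag(matrix(rnorm(8), 2, 4), "A"),
               B = tiny_bag(matrix(rnorm(8), 2, 4), "B"),
               C = tiny_bag(matrix(rnorm(8), 2, 4), "C"))
  empty <- list(A = region_mask("A", integer(0)),
                B = region_mask("B", integer(0)),
                C = region_mask("C", integer(0)))
  # empty masks: removal changes nothing, all deltas 0 -> flagged degenerate
  res <- suppressWarnings(necessity_test(mod, bags, empty))
  expect_true(all(res$slides$delta == 0))
  expect_true(is.na(res$cohens_d))
  # sufficiency with empty masks excludes every slide
  expect_error(suppressMessages(sufficiency_test(mod, bags, empty)),
               "fewer than 2")
})

test_that("greedy search matches the per-iteration argmax oracle", {
  # stub model scores a bag by the mean of feature column 1
  donor <- tiny_bag(matrix(c(5, 1, 3, 0, 0, 0), 3, 2), "donor")
  recipient <- tiny_bag(matrix(c(-1, -1, 0, 0), 2, 2), "recipient")
  trace <- greedy_sufficiency_search(stub_mean_model, donor, recipient,
                                     high_threshold = 100)
  # donor column-1 values are 5, 1, 3: the first pick must be patch 1,
  # and with < 4 donor patches the budget is forced to 1
  expect_equal(trace$selected, 1L)
  expect_equal(trace$budget, 1L)
  expect_equal(trace$stop_reason, "exhausted_budget")
  expect_equal(trace$predictions, mean(c(-1, -1, 5)))
})

test_that("greedy search stop rules fire in the right order", {
  set.seed(21)
  donor <- tiny_bag(cbind(rnorm(20, 5), rnorm(20)), "donor")
  recipient <- tiny_bag(cbind(rnorm(8, -2), rnorm(8)), "recipient")
  # already above threshold: empty trace
  high <- greedy_sufficiency_search(stub_mean_model, donor, recipient,
                                    high_threshold = -5)
  expect_length(high$selected, 0)
  expect_equal(high$stop_reason, "reached_threshold")
  # unreachable threshold with improvement disabled: full quarter budget
  full <- greedy_sufficiency_search(stub_mean_model, donor, recipient,
                                    high_threshold = 1e6,
                                    stop_on_no_improvement = FALSE)
  expect_length(full$selected, 20 %/% 4)
  expect_equal(full$stop_reason, "exhausted_budget")
  # every step must match an exhaustive argmax oracle
  sel <- integer(0); cur <- recipient
  for (step in seq_along(full$selected)) {
    remaining <- setdiff(1:20, sel)
    preds <- vapply(remaining, function(j) {
      stub_mean_model(insert_patches(cur, donor$features[j, , drop = FALSE]))
    }, numeric(1))
    best <- remaining[which.max(preds)]
    expect_equal(full$selected[step], best)
    sel <- c(sel, best)
    cur <- insert_patches(cur, donor$features[best, , drop = FALSE])
  }
  # the mean model's trace rises monotonically with high-mean donors
  expect_true(all(diff(c(full$initial_prediction, full$predictions)) > 0))
})

test_that("greedy search stops when nothing improves", {
  donor <- tiny_bag(cbind(c(-5, -4, -6, -3, -7, -2, -8, -1), rnorm(8)),
                    "donor")
  recipient <- tiny_bag(cbind(c(3, 3, 3), rnorm(3)), "recipient")
  trace <- greedy_sufficiency_search(stub_mean_model, donor, recipient,
                                     high_threshold = 100)
  expect_length(trace$selected, 0)
  expect_equal(trace$stop_reason, "no_improvement")
})

test_that("transfer reports paired predictions per recipient", {
  recips <- list(R1 = tiny_bag(cbind(c(0, 0), c(1, 1)), "R1"),
                 R2 = tiny_bag(cbind(c(-1, 1), c(0, 0)), "R2"))
  res <- transfer_test(stub_mean_model, cbind(c(4, 4), c(0, 0)), recips)
  expect_equal(nrow(res), 2)
  expect_equal(res$augmented - res$original, res$delta)
  expect_true(all(res$delta > 0))
  # inserting a bag's own mean-preserving patches changes the mean model by 0
  own <- transfer_test(stub_mean_model, recips$R1$features, recips["R1"])
  expect_equal(own$delta, 0)
  # empty recipient list -> empty report
  expect_equal(nrow(transfer_test(stub_mean_model, cbind(1, 1), list())), 0)
  expect_error(transfer_test(stub_mean_model, matrix(0, 0, 2), recips),
               "non-empty")
})
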