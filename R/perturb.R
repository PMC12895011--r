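#' Remove or keep patches of a bag
#'
#' Non-destructive bag surgery for perturbation experiments:
#' `remove_patches()` drops the given rows, `keep_only()` restricts the bag
#' to them; row order is preserved in both cases and the original bag is
#' untouched. Removing the complement of a set is identical to keeping it.
#'
#' @param bag An [embedding_bag()].
#' @param indices 1-based patch row indices. `remove_patches()` must leave
#'   at least one patch; `keep_only()` requires a non-empty set.
#' @return A new [embedding_bag()].
#' @export
remove_patches <- function(bag, indices) {
  stopifnot(inherits(bag, "embedding_bag"))
  n <- n_patches(bag)
  indices <- unique(as.integer(indices))
  if (length(indices) && any(indices < 1L | indices > n)) {
    stop("patch indices out of range", call. = FALSE)
  }
  keep <- setdiff(seq_len(n), indices)
  if (length(keep) == 0L) {
    stop("removal would leave an empty bag", call. = FALSE)
  }
  keep_only(bag, keep)
}

#' @rdname remove_patches
#' @export
keep_only <- function(bag, indices) {
  stopifnot(inherits(bag, "embedding_bag"))
  n <- n_patches(bag)
  indices <- unique(as.integer(indices))
  if (length(indices) == 0L) stop("cannot keep an empty patch set", call. = FALSE)
  if (any(indices < 1L | indices > n)) {
    stop("patch indices out of range", call. = FALSE)
  }
  indices <- sort(indices)
  embedding_bag(bag$features[indices, , drop = FALSE],
                bag$coords[indices, , drop = FALSE],
                bag$geometry, bag$slide_id, bag$encoder_id)
}

#' Insert donor patch features into a bag
#'
#' Appends feature rows to a bag. Because the model is permutation-invariant
#' the spatial placement of inserted patches is irrelevant to prediction;
#' for bookkeeping the new rows are laid out on synthetic grid rows appended
#' below the original slide extent (the recorded slide height grows
#' accordingly).
#'
#' @param bag An [embedding_bag()].
#' @param features Numeric matrix of donor patch features (columns matching
#'   the bag).
#' @return A new [embedding_bag()] with the rows appended at the end.
#' @export
insert_patches <- function(bag, features) {
  stopifnot(inherits(bag, "embedding_bag"))
  features <- rbind(features)
  if (ncol(features) != ncol(bag$features)) {
    stop("inserted features must match the bag's embedding dimension",
         call. = FALSE)
  }
  m <- nrow(features)
  s <- bag$geometry$side_px
  per_row <- max(1L, bag$geometry$width_px %/% s)
  extra_rows <- ceiling(m / per_row)
  g <- bag$geometry
  geom <- slide_geometry(g$width_px, g$height_px + extra_rows * s,
                         g$mpp, g$patch_um)
  k <- seq_len(m) - 1L
  new_coords <- data.frame(x = (k %% per_row) * s,
                           y = g$height_px + (k %/% per_row) * s)
  embedding_bag(rbind(bag$features, features),
                rbind(bag$coords, new_coords),
                geom, bag$slide_id, bag$encoder_id)
}

# Scalar risk prediction for a single bag: an abmil fit (classification ->
# positive-class probability, regression -> continuous score) or any
# function(bag) -> numeric.
.predict_risk <- function(model, bag) {
  if (inherits(model, "abmil")) {
    predict(model, bag, type = "response")[1]
  } else if (is.function(model)) {
    as.numeric(model(bag))
  } else {
    stop("model must be an abmil fit or a function(bag) -> numeric",
         call. = FALSE)
  }
}

#' Paired Cohen's d
#'
#' Effect size for paired perturbation deltas: `mean(deltas) / sd(deltas)`
#' with the sample (n - 1) standard deviation. Scale-invariant. When every
#' delta is equal the standard deviation is zero and the effect size is
#' undefined: `NA` is returned with a warning.
#'
#' @param deltas Numeric vector of paired differences, `n >= 2`.
#' @return Cohen's d (or `NA` when undefined).
#' @export
cohens_d_paired <- function(deltas) {
  stopifnot(length(deltas) >= 2)
  s <- stats::sd(deltas)
  if (s == 0) {
    warning("all deltas are equal; Cohen's d undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(deltas) / s
}

# Shared machinery of the necessity / sufficiency tests.
.perturbation_test <- function(model, bags, masks, inclusion_threshold,
                               mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  stopifnot(is.list(bags), is.list(masks))
  ids <- names(bags)
  if (is.null(ids)) ids <- as.character(seq_along(bags))
  rows <- list(); n_skipped <- 0L
  for (i in seq_along(bags)) {
    bag <- bags[[i]]
    mask <- masks[[ids[i]]]
    if (is.null(mask)) mask <- masks[[i]]
    idx <- if (inherits(mask, "region_mask")) {
      patches_intersecting_mask(bag, mask)
    } else {
      as.integer(mask)
    }
    orig <- .predict_risk(model, bag)
    if (!(orig > inclusion_threshold)) next  # strictly greater, per protocol
    if (mode == "remove") {
      if (length(idx) == 0L) {
        pert <- orig                      # nothing to remove
      } else if (length(idx) >= n_patches(bag)) {
        n_skipped <- n_skipped + 1L       # mask covers the whole slide
        next
      } else {
        pert <- .predict_risk(model, remove_patches(bag, idx))
      }
    } else {
      if (length(idx) == 0L) {            # empty mask: nothing to keep
        n_skipped <- n_skipped + 1L
        next
      }
      pert <- .predict_risk(model, keep_only(bag, idx))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      slide_id = ids[i], original = orig, perturbed = pert,
      delta = pert - orig, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " slide(s) excluded (degenerate mask)")
  }
  if (length(rows) < 2L) {
    stop("fewer than 2 eligible slides for the perturbation test",
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  deltas <- tab$delta
  if (stats::sd(deltas) == 0) {
    t_stat <- NA_real_; p <- NA_real_
    d <- suppressWarnings(cohens_d_paired(deltas))
    flag <- "degenerate: all deltas equal"
  } else {
    tt <- stats::t.test(deltas)
    t_stat <- unname(tt$statistic); p <- tt$p.value
    d <- cohens_d_paired(deltas)
    flag <- NA_character_
  }
  structure(list(slides = tab, mean_delta = mean(deltas),
                 t_statistic = t_stat, p_value = p, cohens_d = d,
                 n = nrow(tab), n_excluded = n_skipped, flag = flag,
                 mode = mode),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("%s perturbation test on %d slides\n",
              if (x$mode == "remove") "necessity (region removal)"
              else "sufficiency (region-only)", x$n))
  cat(sprintf("  mean delta = %.4g, t = %.3g, p = %.3g, Cohen's d = %.3g\n",
              x$mean_delta, x$t_statistic, x$p_value, x$cohens_d))
  if (!is.na(x$flag)) cat("  [", x$flag, "]\n", sep = "")
  invisible(x)
}

#' Region necessity and sufficiency tests
#'
#' Perturbation tests of whether a masked tissue region (e.g. tumor) drives
#' a model's high-risk predictions. Both tests restrict to slides whose
#' original positive-class probability exceeds `inclusion_threshold`
#' (strictly greater than 0.5 by default). `necessity_test()` removes the
#' masked patches and recomputes the prediction: a necessary region produces
#' systematically negative deltas. `sufficiency_test()` instead keeps only
#' the masked patches: a sufficient region reproduces the original
#' prediction (deltas near or above zero). Slides with degenerate masks (an
#' empty mask in the sufficiency test, or a mask covering the whole slide in
#' the necessity test) are excluded with a logged count. Deltas
#' `perturbed - original` are summarized by a two-sided paired t-test and
#' paired Cohen's d.
#'
#' @param model A fitted classification [abmil()] model, or any
#'   `function(bag) -> numeric` risk scorer.
#' @param bags Named list of [embedding_bag()] objects.
#' @param masks List of [region_mask()] objects (or raw index vectors),
#'   matched to bags by name or position.
#' @param inclusion_threshold Minimum original prediction for a slide to
#'   enter the test (strict inequality).
#' @return Object of class `perturbation_result`: per-slide table
#'   (`original`, `perturbed`, `delta`), `mean_delta`, `t_statistic`,
#'   `p_value`, `cohens_d`, `n`, `n_excluded`.
#' @export
necessity_test <- function(model, bags, masks, inclusion_threshold = 0.5) {
  .perturbation_test(model, bags, masks, inclusion_threshold, "remove")
}

#' @rdname necessity_test
#' @export
sufficiency_test <- function(model, bags, masks, inclusion_threshold = 0.5) {
  .perturbation_test(model, bags, masks, inclusion_threshold, "keep")
}

#' Greedy search for a minimal sufficient patch set
#'
#' Searches for the smallest set of donor patches that flips a low-risk
#' recipient slide to a high-risk prediction. At each iteration every unused
#' donor patch is provisionally inserted into the recipient (together with
#' the patches already selected) and scored by the model; the patch giving
#' the highest predicted score is retained (ties broken toward the lowest
#' donor index). The search stops when the prediction reaches
#' `high_threshold`, when a quarter of the donor's patches have been used
#' (`floor(N_donor / 4)`, at least 1), or — unless disabled — when the best
#' candidate no longer increases the prediction.
#'
#' @param model A fitted regression [abmil()] model or a
#'   `function(bag) -> numeric` scorer.
#' @param donor_bag High-risk donor [embedding_bag()] supplying candidate
#'   patches.
#' @param recipient_bag Low-risk recipient [embedding_bag()].
#' @param high_threshold Score at which the recipient counts as flipped;
#'   defaults to the assay's high-risk cutpoint.
#' @param stop_on_no_improvement Stop when no candidate raises the score
#'   (default `TRUE`); disable to keep inserting the argmax patch until the
#'   threshold or budget rule fires.
#' @return Object of class `search_trace`: `selected` (donor patch indices
#'   in insertion order), `predictions` (score after each insertion),
#'   `initial_prediction`, `stop_reason` (one of `reached_threshold`,
#'   `exhausted_budget`, `no_improvement`), `budget`.
#' @export
greedy_sufficiency_search <- function(model, donor_bag, recipient_bag,
                                      high_threshold = rorp_thresholds[["high"]],
                                      stop_on_no_improvement = TRUE) {
  stopifnot(inherits(donor_bag, "embedding_bag"),
            inherits(recipient_bag, "embedding_bag"))
  n_donor <- n_patches(donor_bag)
  budget <- max(1L, n_donor %/% 4L)
  selected <- integer(0)
  preds <- numeric(0)
  current <- recipient_bag
  pred <- .predict_risk(model, current)
  initial <- pred
  stop_reason <- NULL
  if (pred >= high_threshold) {
    stop_reason <- "reached_threshold"
  }
  while (is.null(stop_reason)) {
    remaining <- setdiff(seq_len(n_donor), selected)
    cand_pred <- vapply(remaining, function(j) {
      .predict_risk(model,
                    insert_patches(current,
                                   donor_bag$features[j, , drop = FALSE]))
    }, numeric(1))
    best <- which.max(cand_pred)  # first maximum: lowest donor index wins ties
    if (stop_on_no_improvement && cand_pred[best] <= pred) {
      stop_reason <- "no_improvement"
      break
    }
    j <- remaining[best]
    current <- insert_patches(current, donor_bag$features[j, , drop = FALSE])
    pred <- cand_pred[best]
    selected <- c(selected, j)
    preds <- c(preds, pred)
    if (pred >= high_threshold) {
      stop_reason <- "reached_threshold"
    } else if (length(selected) >= budget) {
      stop_reason <- "exhausted_budget"
    }
  }
  structure(list(selected = selected, predictions = preds,
                 initial_prediction = initial, stop_reason = stop_reason,
                 budget = budget, donor_id = donor_bag$slide_id,
                 recipient_id = recipient_bag$slide_id),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("greedy sufficiency search %s -> %s: %d/%d patches, stop: %s\n",
              x$donor_id, x$recipient_id, length(x$selected), x$budget,
              x$stop_reason))
  invisible(x)
}

#' Transferability of a discovered patch set
#'
#' Inserts a fixed set of patch features into each recipient bag and reports
#' the paired original and augmented predictions, testing whether patches
#' discovered on one slide generalize to other low/medium-risk slides.
#'
#' @param model A fitted [abmil()] model or `function(bag) -> numeric`.
#' @param patch_features Non-empty numeric matrix of patch features to
#'   insert.
#' @param recipient_bags List of recipient [embedding_bag()] objects (an
#'   empty list yields an empty report).
#' @return Data frame with `slide_id`, `original`, `augmented`, `delta`.
#' @export
transfer_test <- function(model, patch_features, recipient_bags) {
  patch_features <- rbind(patch_features)
  if (nrow(patch_features) == 0L) {
    stop("patch set must be non-empty", call. = FALSE)
  }
  ids <- names(recipient_bags)
  if (is.null(ids)) ids <- as.character(seq_along(recipient_bags))
  rows <- lapply(seq_along(recipient_bags), function(i) {
    bag <- recipient_bags[[i]]
    orig <- .predict_risk(model, bag)
    aug <- .predict_risk(model, insert_patches(bag, patch_features))
    data.frame(slide_id = ids[i], original = orig, augmented = aug,
               delta = aug - orig, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(slide_id = character(0), original = numeric(0),
                      augmented = numeric(0), delta = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
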