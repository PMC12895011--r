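#' Stratified participant-level fold assignment
#'
#' Assigns each participant to one of `k` folds, stratified so the
#' distribution of risk groups is similar across folds. Within each stratum
#' participants are shuffled and dealt cyclically; a running counter across
#' strata keeps overall fold sizes within one participant of each other.
#' All slides of a participant inherit the participant's fold, so no
#' participant can appear in two roles within a cross-validation iteration.
#'
#' @param participant_id Character vector of participant ids (one entry per
#'   participant; duplicates are collapsed together with their group).
#' @param group Stratification label per entry of `participant_id` (e.g. the
#'   ROR-P risk group).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector: fold index in `1..k` per participant.
#' @export
make_folds <- function(participant_id, group, k = 10, seed = 1L) {
  stopifnot(length(participant_id) == length(group))
  pid <- as.character(participant_id)
  first <- !duplicated(pid)
  pids <- pid[first]
  grp <- as.character(group)[first]
  if (k > length(pids)) {
    stop(sprintf("k = %d folds but only %d participants", k, length(pids)),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- integer(length(pids))
  names(fold) <- pids
  counter <- 0L
  for (g in sample(unique(grp))) {
    members <- sample(pids[grp == g])
    fold[members] <- (counter + seq_along(members) - 1L) %% k + 1L
    counter <- counter + length(members)
  }
  fold
}

#' Participant-stratified k-fold cross-validation of an ABMIL model
#'
#' Runs the full cross-validated training workflow: participants are split
#' into `k` stratified folds; in iteration `i`, fold `i` is the test set,
#' one of the remaining folds is the validation set used for early stopping,
#' and the other `k - 2` folds form the training set. Every slide receives
#' exactly one out-of-fold test prediction, and a participant's slides share
#' a single role per iteration, so no participant is ever trained or
#' optimized on while also being tested.
#'
#' @param cohort A `wsi_cohort` (see [simulate_cohort()]), or any list with
#'   `bags` (named list of bags keyed by `slide_id`) and `clinical` (data
#'   frame with `participant_id`, `slide_id`, `rorp_score`, `rorp_group`,
#'   `er_her2_eligible`).
#' @param task `"classification"` (high vs low/medium) or `"regression"`
#'   (continuous ROR-P).
#' @param k Number of folds (default 10).
#' @param config An [abmil_config()].
#' @param seed Master seed; fold assignment and the per-fold model seeds are
#'   derived from it.
#' @return Object of class `abmil_cv`: list with `predictions` (one row per
#'   slide: ids, fold, logits/score, `prob_high` for classification,
#'   eligibility flag, label), `val_predictions` (pooled validation-set
#'   predictions across folds, for threshold selection), `models` (the `k`
#'   fitted [abmil()] models), `folds`, `task`.
#' @export
crossval_abmil <- function(cohort, task = c("classification", "regression"),
                           k = 10, config = abmil_config(), seed = 1L) {
  task <- match.arg(task)
  cl <- cohort$clinical
  stopifnot(all(cl$slide_id %in% names(cohort$bags)))
  folds <- make_folds(cl$participant_id, cl$rorp_group, k = k,
                      seed = as.integer(seed))
  slide_fold <- folds[cl$participant_id]
  y_all <- if (task == "classification") binarize_rorp_group(cl$rorp_group)
           else cl$rorp_score

  models <- vector("list", k)
  test_rows <- list()
  val_rows <- list()
  for (i in seq_len(k)) {
    val_fold <- i %% k + 1L
    is_test <- slide_fold == i
    is_val <- slide_fold == val_fold
    is_train <- !is_test & !is_val
    if (!any(is_train) || !any(is_val) || !any(is_test)) {
      stop("empty split in cross-validation iteration ", i, call. = FALSE)
    }
    fit <- abmil(cohort$bags[cl$slide_id[is_train]], y_all[is_train],
                 task = task,
                 val_x = cohort$bags[cl$slide_id[is_val]],
                 val_y = y_all[is_val],
                 config = config, seed = as.integer(seed) + 1000L * i)
    models[[i]] <- fit
    pred_block <- function(idx, role) {
      bags_i <- cohort$bags[cl$slide_id[idx]]
      out <- data.frame(slide_id = cl$slide_id[idx],
                        participant_id = cl$participant_id[idx],
                        fold = i, role = role,
                        er_her2_eligible = cl$er_her2_eligible[idx],
                        label = y_all[idx],
                        stringsAsFactors = FALSE)
      if (task == "classification") {
        lg <- predict(fit, bags_i, type = "logits")
        out$logit_low_medium <- lg[, 1]
        out$logit_high <- lg[, 2]
        out$prob_high <- predict(fit, bags_i, type = "response")
        out$score <- out$prob_high
      } else {
        out$score <- predict(fit, bags_i, type = "response")
      }
      out
    }
    test_rows[[i]] <- pred_block(which(is_test), "test")
    val_rows[[i]] <- pred_block(which(is_val), "val")
  }
  predictions <- do.call(rbind, test_rows)
  rownames(predictions) <- NULL
  val_predictions <- do.call(rbind, val_rows)
  rownames(val_predictions) <- NULL
  structure(list(predictions = predictions,
                 val_predictions = val_predictions,
                 models = models, folds = folds, task = task, k = k,
                 seed = as.integer(seed)),
            class = "abmil_cv")
}

#' @export
print.abmil_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated ABMIL (%s): %d out-of-fold predictions\n",
              x$k, x$task, nrow(x$predictions)))
  invisible(x)
}

#' Ensemble inference with cross-validation models
#'
#' Applies all fold models to a (typically external) set of bags and
#' averages: for classification, the mean over models of the
#' softmax-transformed logits (so the ensemble probability vector is itself
#' a probability vector); for regression, the mean of the raw continuous
#' outputs. The result is invariant to the order of the models.
#'
#' @param bags Named list of bags.
#' @param models List of fitted [abmil()] models sharing task and input
#'   dimension (e.g. the `models` element of [crossval_abmil()]).
#' @return Data frame with `slide_id` and `prob_high` (classification) or
#'   `score` (both tasks; for classification `score == prob_high`).
#' @export
ensemble_predict <- function(bags, models) {
  stopifnot(length(models) >= 1)
  task <- models[[1]]$task
  d <- models[[1]]$input_dim
  ok <- vapply(models, function(m) {
    identical(m$task, task) && identical(m$input_dim, d) &&
      identical(m$config$embed_dim, models[[1]]$config$embed_dim) &&
      identical(m$config$attention_dim, models[[1]]$config$attention_dim)
  }, logical(1))
  if (!all(ok)) stop("models have heterogeneous task or shapes", call. = FALSE)
  preds <- vapply(models, function(m) predict(m, bags, type = "response"),
                  numeric(length(bags)))
  avg <- rowMeans(matrix(preds, nrow = length(bags)))
  out <- data.frame(slide_id = if (!is.null(names(bags))) names(bags)
                               else as.character(seq_along(bags)),
                    score = avg, stringsAsFactors = FALSE)
  if (task == "classification") out$prob_high <- avg
  out
}

#' Restrict a prediction table to the clinically eligible subset
#'
#' Filters predictions to ER-positive/HER2-negative participants, the target
#' population for ROR-P testing. Models are trained on the full cohort;
#' evaluation is restricted afterwards.
#'
#' @param predictions Data frame with a `slide_id` column and (optionally)
#'   an `er_her2_eligible` column.
#' @param clinical Optional clinical table supplying `er_her2_eligible` by
#'   `slide_id` when the prediction table lacks it.
#' @return The eligible rows; warns when none remain.
#' @export
restrict_eligible <- function(predictions, clinical = NULL) {
  if (!("er_her2_eligible" %in% names(predictions))) {
    stopifnot(!is.null(clinical))
    predictions$er_her2_eligible <-
      clinical$er_her2_eligible[match(predictions$slide_id, clinical$slide_id)]
  }
  out <- predictions[which(predictions$er_her2_eligible), , drop = FALSE]
  if (nrow(out) == 0L) warning("no eligible rows remain", call. = FALSE)
  rownames(out) <- NULL
  out
}
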