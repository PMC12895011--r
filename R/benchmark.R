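#' Run the full benchmarking workflow on one or more embedding cohorts
#'
#' End-to-end orchestration of the benchmark: for every encoder (a named
#' cohort of bags sharing one clinical table), cross-validate both ABMIL
#' heads, evaluate discrimination on the ER-positive/HER2-negative subset
#' (ROC AUC with a DeLong comparison against the baseline encoder; Pearson
#' r with Meng's z), adjust the pairwise p-values by Benjamini-Hochberg
#' within each (task, metric) family, and evaluate recurrence prediction
#' with the concordance index for three predictors per encoder: the
#' categorical model's high-risk probability, the continuous regression
#' score, and the continuous score thresholded at the assay's high-risk
#' cutpoint. Categorical predictions are binarized at the Youden-optimal
#' threshold selected on the pooled cross-validation validation predictions
#' and frozen before touching test predictions. The report is a
#' deterministic function of the master seed.
#'
#' @param cohorts Named list of `wsi_cohort` objects, one per encoder, all
#'   sharing the same participants and clinical table (the bags differ).
#' @param baseline Name of the baseline encoder the pairwise tests compare
#'   against; must be among `names(cohorts)`.
#' @param k Cross-validation folds.
#' @param config An [abmil_config()].
#' @param seed Master seed; per-encoder and per-head seeds are derived from
#'   it.
#' @return Object of class `mil_benchmark`: `report` (data frame: encoder,
#'   task, metric, value, p_value, p_adj), `thresholds` (per-encoder Youden
#'   thresholds), `cv` (per-encoder cross-validation objects), `log`
#'   (per-stage messages with cohort counts after every filter).
#' @export
run_benchmark <- function(cohorts, baseline, k = 10,
                          config = abmil_config(), seed = 1L) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            !is.null(names(cohorts)), baseline %in% names(cohorts))
  encoders <- names(cohorts)
  clinical <- cohorts[[1]]$clinical
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("benchmark: %d encoders, %d slides, %d participants, baseline '%s'",
       length(encoders), nrow(clinical),
       length(unique(clinical$participant_id)), baseline)

  cv <- list()
  for (i in seq_along(encoders)) {
    enc <- encoders[i]
    enc_seed <- as.integer(seed) + 101L * i
    note("stage crossval [%s]: classification + regression heads", enc)
    cv[[enc]] <- list(
      classification = crossval_abmil(cohorts[[enc]], "classification",
                                      k = k, config = config,
                                      seed = enc_seed),
      regression = crossval_abmil(cohorts[[enc]], "regression",
                                  k = k, config = config,
                                  seed = enc_seed + 1L)
    )
  }

  eligible <- function(tab) restrict_eligible(tab, clinical)
  ecls <- lapply(cv, function(x) eligible(x$classification$predictions))
  ereg <- lapply(cv, function(x) eligible(x$regression$predictions))
  note("stage eligibility: %d of %d slides ER+/HER2- eligible",
       nrow(ecls[[1]]), nrow(clinical))

  # discrimination metrics + pairwise tests vs the baseline
  align <- function(a, b) match(a$slide_id, b$slide_id)
  cls_rows <- lapply(encoders, function(enc) {
    tab <- ecls[[enc]]
    auc <- roc_auc(tab$prob_high, tab$label)
    p <- NA_real_
    if (enc != baseline) {
      base <- ecls[[baseline]][align(tab, ecls[[baseline]]), ]
      p <- delong_test(tab$label, tab$prob_high, base$prob_high)$p_value
    }
    data.frame(encoder = enc, task = "classification", metric = "roc_auc",
               value = auc, p_value = p, stringsAsFactors = FALSE)
  })
  reg_rows <- lapply(encoders, function(enc) {
    tab <- ereg[[enc]]
    r <- pearson_r(tab$score, tab$label)
    p <- NA_real_
    if (enc != baseline) {
      base <- ereg[[baseline]][align(tab, ereg[[baseline]]), ]
      p <- meng_z_from_data(tab$label, tab$score, base$score)$p_value
    }
    data.frame(encoder = enc, task = "regression", metric = "pearson_r",
               value = r, p_value = p, stringsAsFactors = FALSE)
  })

  # survival metrics; Youden threshold from pooled validation predictions
  thresholds <- stats::setNames(numeric(length(encoders)), encoders)
  surv_rows <- list()
  for (enc in encoders) {
    tab <- ecls[[enc]]
    cl <- clinical[match(tab$slide_id, clinical$slide_id), ]
    cen <- censor_at(cl$recurrence_time_years, cl$recurrence_event)
    vtab <- eligible(cv[[enc]]$classification$val_predictions)
    thr <- youden_threshold(vtab$prob_high, vtab$label)
    thresholds[enc] <- thr
    pred_grp <- as.integer(tab$prob_high >= thr)
    lr_p <- tryCatch(
      logrank_test(cen$time, cen$event, pred_grp)$p_value,
      error = function(e) NA_real_)
    rtab <- ereg[[enc]]
    rcl <- clinical[match(rtab$slide_id, clinical$slide_id), ]
    rcen <- censor_at(rcl$recurrence_time_years, rcl$recurrence_event)
    cox_p <- tryCatch(
      cox_univariable(rcen$time, rcen$event, rtab$score)$p_value,
      error = function(e) NA_real_)
    thr_cont <- suppressWarnings(threshold_continuous(rtab$score))
    thr_lr_p <- tryCatch(
      logrank_test(rcen$time, rcen$event, thr_cont)$p_value,
      error = function(e) NA_real_)
    surv_rows[[enc]] <- data.frame(
      encoder = enc, task = "survival",
      metric = c("cindex_categorical", "cindex_continuous",
                 "cindex_thresholded"),
      value = c(concordance_index(cen$time, cen$event, tab$prob_high),
                concordance_index(rcen$time, rcen$event, rtab$score),
                tryCatch(concordance_index(rcen$time, rcen$event, thr_cont),
                         error = function(e) NA_real_)),
      p_value = c(lr_p, cox_p, thr_lr_p),
      stringsAsFactors = FALSE)
  }
  note("stage survival: C-indices for categorical, continuous and thresholded predictors")

  report <- rbind(do.call(rbind, cls_rows), do.call(rbind, reg_rows),
                  do.call(rbind, surv_rows))
  rownames(report) <- NULL
  # BH families: within each (task, metric), across the pairwise encoder
  # comparisons (survival p-values are per-encoder association tests and are
  # adjusted within their own metric family)
  report$p_adj <- NA_real_
  for (fam in split(seq_len(nrow(report)),
                    paste(report$task, report$metric))) {
    has_p <- fam[!is.na(report$p_value[fam])]
    if (length(has_p)) report$p_adj[has_p] <- bh_adjust(report$p_value[has_p])
  }
  structure(list(report = report, thresholds = thresholds, cv = cv,
                 baseline = baseline, log = log, seed = as.integer(seed)),
            class = "mil_benchmark")
}

#' @export
print.mil_benchmark <- function(x, ...) {
  cat("MIL benchmark report (baseline:", x$baseline, ")\n")
  print(x$report, digits = 3)
  invisible(x)
}

#' Evaluate cross-validation model ensembles on an external cohort
#'
#' Applies the full set of fold models per encoder to a held-out cohort
#' (no training): classification predictions are the mean of the
#' softmax-transformed logits across the fold models, regression
#' predictions the mean of the raw scores. The same metric stack as
#' [run_benchmark()] is then computed on the eligible subset.
#'
#' @param cohort External `wsi_cohort`.
#' @param models Named list (per encoder) of lists with elements
#'   `classification` and/or `regression`, each a list of fitted [abmil()]
#'   models (the fold checkpoints). Missing checkpoints raise an error.
#' @param baseline Baseline encoder name for pairwise tests.
#' @return Object of class `mil_benchmark` (without `cv`), with
#'   `predictions` per encoder.
#' @export
run_external_eval <- function(cohort, models, baseline) {
  stopifnot(inherits(cohort, "wsi_cohort"), is.list(models),
            !is.null(names(models)), baseline %in% names(models))
  encoders <- names(models)
  clinical <- cohort$clinical
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("external evaluation: %d encoders on %d slides",
       length(encoders), nrow(clinical))

  preds <- list()
  for (enc in encoders) {
    mod <- models[[enc]]
    if (is.null(mod$classification) || length(mod$classification) == 0L ||
        is.null(mod$regression) || length(mod$regression) == 0L) {
      stop("missing checkpoints for encoder '", enc, "'", call. = FALSE)
    }
    bags <- cohort$bags[clinical$slide_id]
    pc <- ensemble_predict(bags, mod$classification)
    pr <- ensemble_predict(bags, mod$regression)
    tab <- data.frame(slide_id = clinical$slide_id,
                      participant_id = clinical$participant_id,
                      er_her2_eligible = clinical$er_her2_eligible,
                      label_class = binarize_rorp_group(clinical$rorp_group),
                      label_score = clinical$rorp_score,
                      prob_high = pc$prob_high, score = pr$score,
                      stringsAsFactors = FALSE)
    preds[[enc]] <- tab
  }
  epreds <- lapply(preds, function(tab) restrict_eligible(tab, clinical))
  note("eligibility filter: %d of %d slides retained",
       nrow(epreds[[1]]), nrow(clinical))

  rows <- list()
  for (enc in encoders) {
    tab <- epreds[[enc]]
    base <- epreds[[baseline]][match(tab$slide_id,
                                     epreds[[baseline]]$slide_id), ]
    auc <- roc_auc(tab$prob_high, tab$label_class)
    p_auc <- if (enc == baseline) NA_real_ else
      delong_test(tab$label_class, tab$prob_high, base$prob_high)$p_value
    r <- pearson_r(tab$score, tab$label_score)
    p_r <- if (enc == baseline) NA_real_ else
      meng_z_from_data(tab$label_score, tab$score, base$score)$p_value
    cl <- clinical[match(tab$slide_id, clinical$slide_id), ]
    cen <- censor_at(cl$recurrence_time_years, cl$recurrence_event)
    rows[[enc]] <- data.frame(
      encoder = enc,
      task = c("classification", "regression", "survival", "survival"),
      metric = c("roc_auc", "pearson_r", "cindex_categorical",
                 "cindex_continuous"),
      value = c(auc, r,
                concordance_index(cen$time, cen$event, tab$prob_high),
                concordance_index(cen$time, cen$event, tab$score)),
      p_value = c(p_auc, p_r, NA_real_, NA_real_),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report$p_adj <- NA_real_
  for (fam in split(seq_len(nrow(report)),
                    paste(report$task, report$metric))) {
    has_p <- fam[!is.na(report$p_value[fam])]
    if (length(has_p)) report$p_adj[has_p] <- bh_adjust(report$p_value[has_p])
  }
  structure(list(report = report, predictions = preds, baseline = baseline,
                 log = log),
            class = "mil_benchmark")
}
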