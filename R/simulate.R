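#' Simulate a cohort of embedding bags with planted recurrence-risk signal
#'
#' Generates the data structure the whole pipeline consumes, with known
#' ground truth: per participant a latent continuous ROR-P score `r`, per
#' slide a bag of d-dimensional patch embeddings in which the patches of a
#' "tumor" mask carry a mean shift `beta * r * u` along a cohort-level unit
#' direction `u` (all other patches are isotropic noise), and a recurrence
#' time drawn from an exponential distribution whose log hazard is linear in
#' `r`, administratively censored at `censor_horizon` years.
#'
#' Defaults emulate a realistic study: scores from a normal distribution
#' (location 40, scale 30) truncated to `[-20, 90]`, which reproduces the
#' low/medium/high risk-group mix of a typical breast-cancer study cohort
#' (roughly 16/53/31 percent); 30-60 patches per slide; a tumor fraction between
#' 20 and 40 percent; 65 percent of participants ER-positive/HER2-negative
#' (the clinically eligible evaluation subset); baseline hazard 0.012 per
#' year with log-hazard slope 0.04 per score unit, giving roughly a third of
#' participants an event within the 10-year horizon.
#'
#' @param n_participants Number of participants.
#' @param d Embedding dimension.
#' @param patches_range Integer range `c(min, max)` of patches per slide
#'   (`min >= 2`).
#' @param tumor_fraction_range Range of the per-slide tumor fraction, in
#'   (0, 1); at least one tumor patch is always planted.
#' @param score_mean,score_sd,score_range Location, scale and truncation
#'   support of the latent ROR-P score distribution.
#' @param signal_strength Mean-shift coefficient `beta >= 0` per score unit.
#'   `beta = 0` produces a no-signal cohort (flagged with a message).
#' @param signal_direction Optional unit vector of length `d` to plant the
#'   signal along; drawn at random when `NULL`. Supply the training cohort's
#'   `truth$direction` when generating an external cohort meant to be
#'   exchangeable with it (the same "encoder" must embed signal the same
#'   way in both cohorts).
#' @param noise_sd Isotropic feature noise standard deviation (> 0).
#' @param baseline_hazard,log_hazard_coef Exponential recurrence model:
#'   `T ~ Exp(rate = baseline_hazard * exp(log_hazard_coef * r))`.
#' @param censor_horizon Administrative censoring horizon in years.
#' @param eligible_fraction Fraction of participants flagged
#'   ER-positive/HER2-negative (evaluation-eligible).
#' @param slides_per_participant Slides per participant (all sharing the
#'   participant's latent score); > 1 exercises leakage-safe splitting.
#' @param mpp,patch_um Slide resolution and physical patch size used to lay
#'   patches on a pixel grid.
#' @param encoder_id Encoder label stamped on every bag.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return Object of class `wsi_cohort`: list with `bags` (named list of
#'   [embedding_bag()]), `masks` (named list of [region_mask()] index sets —
#'   exactly the rows carrying the planted shift), `clinical` (one row per
#'   slide: `participant_id`, `slide_id`, `rorp_score`, `rorp_group`,
#'   `er_her2_eligible`, `recurrence_time_years`, `recurrence_event`),
#'   `truth` (latent scores, signal direction `u`, per-slide signal index
#'   sets) and `config`.
#' @export
simulate_cohort <- function(n_participants = 200, d = 32,
                            patches_range = c(30, 60),
                            tumor_fraction_range = c(0.2, 0.4),
                            score_mean = 40, score_sd = 30,
                            score_range = c(-20, 90),
                            signal_strength = 0.05, noise_sd = 1,
                            signal_direction = NULL,
                            baseline_hazard = 0.012, log_hazard_coef = 0.04,
                            censor_horizon = 10, eligible_fraction = 0.65,
                            slides_per_participant = 1,
                            mpp = 0.5, patch_um = 128,
                            encoder_id = "synthetic", seed = 1L) {
  stopifnot(n_participants >= 1, d >= 1, patches_range[1] >= 2,
            patches_range[2] >= patches_range[1],
            tumor_fraction_range[1] > 0, tumor_fraction_range[2] < 1,
            noise_sd > 0, signal_strength >= 0, score_sd > 0,
            baseline_hazard > 0, censor_horizon > 0)
  if (signal_strength == 0) {
    message("signal_strength is 0: cohort carries no planted signal")
  }
  set.seed(as.integer(seed))

  # latent scores from a truncated normal spanning all three risk bins
  lo <- stats::pnorm(score_range[1], score_mean, score_sd)
  hi <- stats::pnorm(score_range[2], score_mean, score_sd)
  r <- stats::qnorm(stats::runif(n_participants, lo, hi), score_mean, score_sd)

  if (is.null(signal_direction)) {
    u <- stats::rnorm(d)
  } else {
    stopifnot(length(signal_direction) == d)
    u <- as.numeric(signal_direction)
  }
  u <- u / sqrt(sum(u^2))

  # exponential recurrence with log-linear hazard, censored at the horizon
  rate <- baseline_hazard * exp(log_hazard_coef * r)
  t_raw <- stats::rexp(n_participants, rate = rate)
  event <- as.integer(t_raw <= censor_horizon)
  time <- pmin(t_raw, censor_horizon)

  eligible <- stats::runif(n_participants) < eligible_fraction

  # pixel grid large enough for the biggest bag
  ncols <- ceiling(sqrt(patches_range[2]))
  nrows <- ceiling(patches_range[2] / ncols)
  side <- as.integer(round(patch_um / mpp))
  geom <- slide_geometry(ncols * side, nrows * side, mpp, patch_um)
  grid <- compute_patch_grid(geom)

  pid <- sprintf("P%04d", seq_len(n_participants))
  bags <- list(); masks <- list(); signal_sets <- list()
  rows <- vector("list", n_participants * slides_per_participant)
  k <- 0L
  for (i in seq_len(n_participants)) {
    for (s in seq_len(slides_per_participant)) {
      k <- k + 1L
      sid <- if (slides_per_participant == 1) pid[i] else
        sprintf("%s_S%d", pid[i], s)
      n <- sample(patches_range[1]:patches_range[2], 1L)
      frac <- stats::runif(1, tumor_fraction_range[1], tumor_fraction_range[2])
      n_tumor <- max(1L, round(frac * n))
      tumor_idx <- sort(sample.int(n, n_tumor))
      x <- matrix(stats::rnorm(n * d, sd = noise_sd), nrow = n)
      if (signal_strength > 0) {
        x[tumor_idx, ] <- x[tumor_idx, , drop = FALSE] +
          tcrossprod(rep(signal_strength * r[i], n_tumor), u)
      }
      bags[[sid]] <- embedding_bag(x, grid[seq_len(n), ], geom, sid, encoder_id)
      masks[[sid]] <- region_mask(sid, patch_indices = tumor_idx)
      signal_sets[[sid]] <- tumor_idx
      rows[[k]] <- data.frame(participant_id = pid[i], slide_id = sid,
                              rorp_score = r[i],
                              er_her2_eligible = eligible[i],
                              recurrence_time_years = time[i],
                              recurrence_event = event[i],
                              stringsAsFactors = FALSE)
    }
  }
  clinical <- do.call(rbind, rows)
  clinical$rorp_group <- categorize_rorp(clinical$rorp_score)
  clinical <- clinical[, c("participant_id", "slide_id", "rorp_score",
                           "rorp_group", "er_her2_eligible",
                           "recurrence_time_years", "recurrence_event")]
  structure(
    list(bags = bags, masks = masks, clinical = clinical,
         truth = list(scores = stats::setNames(r, pid), direction = u,
                      signal_sets = signal_sets),
         config = list(n_participants = n_participants, d = d,
                       patches_range = patches_range,
                       tumor_fraction_range = tumor_fraction_range,
                       score_mean = score_mean, score_sd = score_sd,
                       score_range = score_range,
                       signal_strength = signal_strength, noise_sd = noise_sd,
                       baseline_hazard = baseline_hazard,
                       log_hazard_coef = log_hazard_coef,
                       censor_horizon = censor_horizon,
                       eligible_fraction = eligible_fraction,
                       slides_per_participant = slides_per_participant,
                       seed = seed),
         null_permuted = FALSE),
    class = "wsi_cohort"
  )
}

#' @export
print.wsi_cohort <- function(x, ...) {
  cat(sprintf("synthetic WSI cohort: %d slides, %d participants, d = %d%s\n",
              nrow(x$clinical), length(unique(x$clinical$participant_id)),
              x$config$d, if (isTRUE(x$null_permuted)) " (null-permuted)" else ""))
  print(table(x$clinical$rorp_group))
  invisible(x)
}

#' Null cohort: labels permuted against bags
#'
#' Destroys every bag-label association while preserving all marginals, for
#' type-I-error calibration of the evaluation stack. Participant-level
#' outcome columns (score, group, eligibility, recurrence time/event) are
#' re-dealt across participants by a random permutation; bags and masks are
#' untouched.
#'
#' @param cohort A `wsi_cohort`, or arguments for [simulate_cohort()] when
#'   called via `generate_null_cohort(...)`.
#' @param seed Integer seed for the permutation.
#' @return A `wsi_cohort` with `null_permuted = TRUE`.
#' @export
permute_cohort_labels <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "wsi_cohort"))
  set.seed(as.integer(seed))
  cl <- cohort$clinical
  pids <- unique(cl$participant_id)
  perm <- sample(pids)
  map <- stats::setNames(match(perm, pids), pids)
  src <- map[cl$participant_id]
  part <- cl[match(pids, cl$participant_id), ]  # one row per participant
  for (col in c("rorp_score", "rorp_group", "er_her2_eligible",
                "recurrence_time_years", "recurrence_event")) {
    cl[[col]] <- part[[col]][src]
  }
  cohort$clinical <- cl
  cohort$null_permuted <- TRUE
  cohort
}

#' @rdname permute_cohort_labels
#' @param ... Passed to [simulate_cohort()].
#' @export
generate_null_cohort <- function(..., seed = 1L) {
  cohort <- simulate_cohort(..., seed = seed)
  permute_cohort_labels(cohort, seed = as.integer(seed) + 1L)
}
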