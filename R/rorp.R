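#' ROR-P risk-group thresholds
#'
#' Fixed cutpoints of the PAM50 ROR-P assay separating low, medium and high
#' risk of recurrence: low `< 11.76471`, medium `>= 11.76471` and
#' `< 52.94118`, high `>= 52.94118`.
#'
#' @format Named numeric vector with elements `medium` and `high` (the left
#'   boundaries of those groups).
#' @export
rorp_thresholds <- c(medium = 11.76471, high = 52.94118)

#' Categorize a continuous ROR-P score
#'
#' Applies the assay's fixed cutpoints: scores below 11.76471 are `low`,
#' scores in `[11.76471, 52.94118)` are `medium`, scores at or above
#' 52.94118 are `high`. Each left boundary is inclusive. Vectorized; the
#' mapping is total and monotone in the score.
#'
#' @param score Numeric vector of finite ROR-P scores.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' categorize_rorp(c(0, 11.76471, 52.94118))
#' @export
categorize_rorp <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("ROR-P scores must be finite numbers", call. = FALSE)
  }
  cut(score,
      breaks = c(-Inf, rorp_thresholds[["medium"]], rorp_thresholds[["high"]], Inf),
      labels = c("low", "medium", "high"),
      right = FALSE)
}

#' Binarize a risk group for classification
#'
#' High ROR-P is the positive category; low and medium collapse to 0.
#'
#' @param group Character or factor vector with values in
#'   `c("low", "medium", "high")`.
#' @return Integer vector of 0/1.
#' @export
binarize_rorp_group <- function(group) {
  group <- as.character(group)
  bad <- !(group %in% c("low", "medium", "high"))
  if (any(bad)) {
    stop("unknown risk group: ", paste(unique(group[bad]), collapse = ", "),
         call. = FALSE)
  }
  as.integer(group == "high")
}

#' Threshold continuous risk predictions at the assay's high-risk cutpoint
#'
#' Maps predicted continuous ROR-P scores to the binary high vs low/medium
#' contrast using the same threshold the transcriptomic assay applies
#' (`>= 52.94118` is high). Used to compare categorical models with their
#' thresholded continuous counterparts on an equal footing.
#'
#' @param scores Numeric vector of predicted continuous ROR-P scores.
#' @param threshold High-risk cutpoint; defaults to the assay value.
#' @return Integer vector of 0/1 (1 = high). Warns when the result has a
#'   single class, which degenerate downstream group comparisons cannot use.
#' @export
threshold_continuous <- function(scores, threshold = rorp_thresholds[["high"]]) {
  stopifnot(is.numeric(scores))
  out <- as.integer(scores >= threshold)
  if (length(out) > 0L && length(unique(out)) == 1L) {
    warning("thresholded predictions contain a single group", call. = FALSE)
  }
  out
}
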