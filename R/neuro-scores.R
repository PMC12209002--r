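#' Classify post-surgical cognitive deficit
#'
#' A subject is classified as having a cognitive deficit at a timepoint if
#' ANY score is on the impaired side of its clinical cutoff after orientation
#' normalization: above the cutoff for `higher_worse` scores (timed tests),
#' below it for `higher_better` scores. A score exactly at its cutoff is NOT
#' impaired (strict inequality). The default timepoint is one week after
#' surgery, the stage at which the deficit subgroup is defined.
#'
#' @param behavior Behavior tibble (`subject`, `timepoint`, `score`, `value`,
#'   `cutoff`, `orientation`).
#' @param timepoint Timepoint label to classify at (default `"1w"`).
#' @param scores Score names that must all be present (default: all scores
#'   occurring in the table).
#' @return A tibble (`subject`, `deficit`, plus one logical
#'   `impaired_<score>` column per score).
#' @export
classify_deficit <- function(behavior, timepoint = "1w", scores = NULL) {
  scores <- scores %||% sort(unique(behavior$score))
  tp <- dplyr::filter(behavior, .data$timepoint == !!timepoint,
    .data$score %in% scores)
  need <- tidyr::expand_grid(subject = unique(behavior$subject), score = scores)
  miss <- dplyr::anti_join(need, tp, by = c("subject", "score"))
  if (nrow(miss) > 0) {
    stop(sprintf("missing score(s) at timepoint '%s': %s.", timepoint,
      paste(paste(miss$subject, miss$score, sep = "/"), collapse = ", ")),
      call. = FALSE)
  }
  tp <- dplyr::mutate(tp, impaired = ifelse(.data$orientation == "higher_worse",
    .data$value > .data$cutoff, .data$value < .data$cutoff))
  wide <- tp |>
    dplyr::select("subject", "score", "impaired") |>
    tidyr::pivot_wider(names_from = "score", values_from = "impaired",
      names_prefix = "impaired_")
  flags <- tp |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(deficit = any(.data$impaired), .groups = "drop")
  dplyr::left_join(flags, wide, by = "subject")
}

#' Longitudinal change in behavioral scores
#'
#' Per subject and score, `value(to) - value(from)` — by default the change
#' from pre-surgery to the 3-month follow-up. Because TMT B-A is the
#' difference of TMT-B and TMT-A at every timepoint, its delta equals the
#' difference of the TMT-B and TMT-A deltas by construction.
#'
#' @param behavior Behavior tibble.
#' @param from,to Timepoint labels.
#' @return A tibble (`subject`, `score`, `delta`, `orientation`).
#' @export
delta_scores <- function(behavior, from = "pre", to = "3m") {
  present <- unique(behavior$timepoint)
  if (!all(c(from, to) %in% present)) {
    stop(sprintf("timepoint(s) missing from behavior table: %s.",
      paste(setdiff(c(from, to), present), collapse = ", ")), call. = FALSE)
  }
  wide <- behavior |>
    dplyr::filter(.data$timepoint %in% c(from, to)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value",
      id_cols = c("subject", "score", "orientation"))
  if (any(is.na(wide[[from]]) | is.na(wide[[to]]))) {
    bad <- wide$subject[is.na(wide[[from]]) | is.na(wide[[to]])]
    stop(sprintf("missing timepoint values for subject(s): %s.",
      paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  wide |>
    dplyr::mutate(delta = .data[[to]] - .data[[from]]) |>
    dplyr::select("subject", "score", "delta", "orientation")
}
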