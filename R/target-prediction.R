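#' Prediction plan of a pass classifier
#'
#' Each trained pass classifier predicts the target percentage of the six
#' spatial locations it was not trained on: the remaining locations of its
#' own pass plus the two locations the opposite pass classifier was trained
#' on (the cross-pass check — the only way to score a classifier's own
#' training locations is with the opposite classifier).
#'
#' @param pass `"Pass1"` or `"Pass2"`.
#' @return A tibble with columns `label`, `hemisphere`.
#' @export
plan_predictions <- function(pass = c("Pass1", "Pass2")) {
  pass <- match.arg(pass)
  if (pass == "Pass1") {
    tibble::tibble(
      label = c("C_Pass1", "C_Pass1", "B", "D", "A", "E"),
      hemisphere = c("Left", "Right", "Right", "Left", "Left", "Right"))
  } else {
    tibble::tibble(
      label = c("C_Pass2", "C_Pass2", "A", "E", "B", "D"),
      hemisphere = c("Left", "Right", "Right", "Left", "Left", "Right"))
  }
}

#' Per-location target percentage
#'
#' Classifies every 5-s segment of each requested location with a trained
#' pipeline and reports the fraction classified in-target as a percentage
#' (the "Target %"). Percentages are exact multiples of
#' `100 / n_segments`.
#'
#' @param pipeline An `lfp_pipeline`.
#' @param features Feature tibble (from [extract_features()]) covering the
#'   locations of interest; must have `label` and `hemisphere` columns.
#' @param locations Tibble of `label`/`hemisphere` rows to predict
#'   (default: the pipeline's pass plan).
#' @param involvement Involvement tibble used to annotate grades.
#' @return A tibble with one row per location: `label`, `hemisphere`,
#'   `pair`, `grade`, `grade_rank`, `n_segments`, `n_in_target`,
#'   `target_pct`.
#' @export
predict_target_pct <- function(pipeline, features,
                               locations = plan_predictions(pipeline$pass),
                               involvement = default_involvement()) {
  stopifnot(inherits(pipeline, "lfp_pipeline"), is.data.frame(features))
  locs <- lead_locations(involvement)
  rows <- dplyr::inner_join(features, locations, by = c("label", "hemisphere"))
  missing <- dplyr::anti_join(locations,
                              dplyr::distinct(rows, .data$label, .data$hemisphere),
                              by = c("label", "hemisphere"))
  if (nrow(missing) > 0L) {
    stop("no segments for location(s): ",
         paste(paste0(missing$label, "-", missing$hemisphere), collapse = ", "))
  }
  rows$.pred <- predict(pipeline, rows)
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$label, .data$hemisphere),
    n_segments = dplyr::n(),
    n_in_target = sum(.data$.pred == 1L),
    target_pct = 100 * .data$n_in_target / .data$n_segments,
    .groups = "drop"
  )
  out <- dplyr::inner_join(
    out, dplyr::select(locs, "label", "hemisphere", "pair", "grade", "grade_rank"),
    by = c("label", "hemisphere"))
  dplyr::select(out, "label", "hemisphere", "pair", "grade", "grade_rank",
                "n_segments", "n_in_target", "target_pct")
}

#' Combined two-classifier target report
#'
#' Emits the 12-location report: each pass classifier predicts its own
#' plan, so every location is scored exactly once, and `cross_pass` marks
#' the four cells where a classifier scored the opposite pass's training
#' locations.
#'
#' @param pipelines Named list with elements `Pass1` and `Pass2` (each an
#'   `lfp_pipeline`).
#' @inheritParams predict_target_pct
#' @return A tibble with one row per location, including `predicted_by`
#'   and `cross_pass` columns.
#' @export
target_report <- function(pipelines, features,
                          involvement = default_involvement()) {
  stopifnot(all(c("Pass1", "Pass2") %in% names(pipelines)))
  out <- purrr::map_dfr(c("Pass1", "Pass2"), function(p) {
    dplyr::mutate(
      predict_target_pct(pipelines[[p]], features,
                         locations = plan_predictions(p),
                         involvement = involvement),
      predicted_by = p)
  })
  map <- .pair_location_map()
  own_pass <- map$pass[match(out$label, map$label)]
  out$cross_pass <- own_pass != out$predicted_by
  dplyr::arrange(out, .data$hemisphere, .data$label)
}

#' Rank contacts by target signature
#'
#' Orders each hemisphere's locations by decreasing target percentage and
#' maps them back to bipolar contact pairs: the recommendation is the
#' pair(s) whose LFP most resembles the in-target training signal. Tied
#' percentages share a rank. A per-contact view (max over the pairs
#' containing each contact) is included as a secondary aggregation.
#'
#' @param predictions A prediction tibble from [predict_target_pct()] or
#'   [target_report()].
#' @return A list with `pairs` (ranked location tibble with a `rank`
#'   column, ties sharing the minimum rank) and `contacts` (per-contact
#'   best target percentage).
#' @export
rank_contacts <- function(predictions) {
  stopifnot(is.data.frame(predictions), nrow(predictions) >= 1L)
  ranked <- dplyr::mutate(
    dplyr::group_by(predictions, .data$hemisphere),
    rank = rank(-.data$target_pct, ties.method = "min"))
  ranked <- dplyr::arrange(dplyr::ungroup(ranked),
                           .data$hemisphere, .data$rank, .data$label)
  contacts <- tidyr::separate(
    dplyr::select(ranked, "hemisphere", "pair", "target_pct"),
    "pair", into = c("lo", "hi"), sep = "-", convert = TRUE)
  contacts <- tidyr::pivot_longer(contacts, c("lo", "hi"),
                                  values_to = "contact")
  contacts <- dplyr::summarise(
    dplyr::group_by(contacts, .data$hemisphere, .data$contact),
    best_target_pct = max(.data$target_pct), .groups = "drop")
  list(pairs = ranked,
       contacts = dplyr::arrange(contacts, .data$hemisphere,
                                 -.data$best_target_pct))
}
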