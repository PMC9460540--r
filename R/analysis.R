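#' Run the full two-classifier target analysis
#'
#' End-to-end convenience wrapper: simulates (or accepts) a bilateral
#' session, segments it, extracts the 17-feature table for every channel,
#' trains the Pass1 and Pass2 classifiers on their respective
#' in-target/off-target location pairs, and produces the combined
#' 12-location target report plus per-hemisphere contact ranking.
#'
#' @param seed Integer seed controlling the simulation and the nested
#'   splits / classifier initialization.
#' @param config A [synth_config()]; ignored when `session` is given.
#' @param session Optional [lfp_session()] to analyse instead of a
#'   simulated one.
#' @param involvement Involvement tibble (see [default_involvement()]).
#' @param window_s Segment length in seconds.
#' @param var_threshold PCA explained-variance threshold.
#' @param scale Z-score features before PCA?
#' @return An object of class `lfp_analysis` with elements `features`,
#'   `pipelines` (named list of `lfp_pipeline`), `report` (see
#'   [target_report()]), `ranking` (see [rank_contacts()]) and `seed`.
#' @examples
#' \donttest{
#' res <- run_target_analysis(seed = 1)
#' glance(res)
#' }
#' @export
run_target_analysis <- function(seed = 1L, config = synth_config(),
                                session = NULL,
                                involvement = default_involvement(),
                                window_s = 5, var_threshold = 0.99,
                                scale = TRUE) {
  if (is.null(session)) {
    session <- simulate_session(config, involvement, seed = seed)
  }
  segments <- segment_session(session, window_s)
  features <- extract_features(segments, session$fs)
  pipelines <- lapply(c(Pass1 = "Pass1", Pass2 = "Pass2"), function(p) {
    labelled <- dplyr::inner_join(features, training_locations(p),
                                  by = c("label", "hemisphere"))
    train_pass_classifier(labelled, pass = p, seed = seed,
                          var_threshold = var_threshold, scale = scale)
  })
  report <- target_report(pipelines, features, involvement)
  structure(
    list(features = features, pipelines = pipelines, report = report,
         ranking = rank_contacts(report), seed = as.integer(seed)),
    class = "lfp_analysis"
  )
}

#' @export
print.lfp_analysis <- function(x, ...) {
  cat("<lfp_analysis>\n")
  for (p in names(x$pipelines)) print(x$pipelines[[p]])
  cat("\nTarget % by location:\n")
  print(as.data.frame(dplyr::select(x$report, "label", "hemisphere", "grade",
                                    "target_pct", "predicted_by")))
  invisible(x)
}

#' @rdname run_target_analysis
#' @param x An `lfp_analysis`.
#' @param ... Unused.
#' @return `glance()` returns one summary row per trained pipeline;
#'   `tidy()` returns the combined target report.
#' @export
glance.lfp_analysis <- function(x, ...) {
  purrr::map_dfr(x$pipelines, glance)
}

#' @rdname run_target_analysis
#' @export
tidy.lfp_analysis <- function(x, ...) x$report
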