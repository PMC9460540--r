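#' Bar chart of the feature ranking
#'
#' Visualizes the pooled-variance t criterion per feature, in ranked
#' order — the discriminability of each of the 17 features for one pass's
#' in-target/off-target contrast.
#'
#' @param ranking A ranking tibble from [rank_features()] (or
#'   `tidy(<lfp_pipeline>)`).
#' @return A ggplot object.
#' @export
plot_feature_ranking <- function(ranking) {
  stopifnot(all(c("feature", "criterion") %in% names(ranking)))
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$criterion),
                               y = .data$criterion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|t| (pooled-variance criterion)",
                  title = "Feature ranking") +
    ggplot2::theme_minimal()
}

#' Target percentage by location
#'
#' Dot plot of the predicted target percentage per spatial location,
#' faceted by hemisphere and colored by involvement grade; cross-pass
#' predictions (a classifier scoring the opposite pass's training
#' locations) are drawn hollow.
#'
#' @param report A report tibble from [target_report()] or
#'   [predict_target_pct()].
#' @return A ggplot object.
#' @export
plot_target_pct <- function(report) {
  stopifnot(all(c("label", "hemisphere", "target_pct") %in% names(report)))
  if (!("cross_pass" %in% names(report))) report$cross_pass <- FALSE
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$label, y = .data$target_pct,
                               colour = .data$grade,
                               shape = .data$cross_pass)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "cross-pass") +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "spatial location", y = "Target %",
                  colour = "involvement") +
    ggplot2::theme_minimal()
}

#' @rdname plot_feature_ranking
#' @param object An `lfp_pipeline`.
#' @param ... Unused.
#' @export
autoplot.lfp_pipeline <- function(object, ...) {
  plot_feature_ranking(object$ranking) +
    ggplot2::labs(subtitle = object$pass)
}

#' @rdname plot_target_pct
#' @param object An `lfp_analysis`.
#' @param ... Unused.
#' @export
autoplot.lfp_analysis <- function(object, ...) {
  plot_target_pct(object$report)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
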