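#' Train a pass classifier end to end
#'
#' Runs the full training methodology on a labelled feature table: ranks
#' the 17 features by the pooled-variance t criterion (reported, not used
#' to drop features), fits the variance-thresholded PCA on the whole
#' labelled dataset, projects it, realizes the nested 80/20 splits, selects
#' the best classifier family at standard parameters on the CV set, sweeps
#' that family's parameter grid, refits on the full outer training set and
#' evaluates on the untouched outer test set.
#'
#' @param features Labelled feature tibble: the 17 feature columns plus a
#'   0/1 `class` column (1 = in-target), e.g. from [extract_features()]
#'   joined with [training_locations()].
#' @param pass `"Pass1"` or `"Pass2"` (metadata only).
#' @param seed Seed controlling the splits and classifier initialization.
#' @param var_threshold PCA explained-variance threshold.
#' @param scale Z-score features before PCA?
#' @return An object of class `lfp_pipeline`: ranking, projection, chosen
#'   family/parameter with CV accuracy tables, fitted model, held-out
#'   metrics and a reproducibility manifest.
#' @export
train_pass_classifier <- function(features, pass = c("Pass1", "Pass2"),
                                  seed = 1L, var_threshold = 0.99,
                                  scale = TRUE) {
  pass <- match.arg(pass)
  stopifnot(is.data.frame(features), "class" %in% names(features))
  ranking <- rank_features(features)
  projection <- fit_projection(features, var_threshold, scale)
  scores <- predict(projection, features)
  y <- as.integer(features$class)
  splits <- make_splits(y, seed)
  sel <- select_family(scores[splits$train2, ], y[splits$train2],
                       scores[splits$cv, ], y[splits$cv], init_seed = seed)
  tune <- tune_family(sel$family, scores[splits$train2, ], y[splits$train2],
                      scores[splits$cv, ], y[splits$cv], init_seed = seed)
  final <- final_fit_evaluate(sel$family, tune$parameter,
                              scores[splits$train, ], y[splits$train],
                              scores[splits$test, ], y[splits$test],
                              init_seed = seed)
  structure(
    list(pass = pass, ranking = ranking, projection = projection,
         family = sel$family, parameter = tune$parameter,
         selection = sel$accuracies, tuning = tune$accuracies,
         model = final$model, metrics = final$metrics, splits = splits,
         seed = as.integer(seed), n = nrow(features)),
    class = "lfp_pipeline"
  )
}

#' @export
print.lfp_pipeline <- function(x, ...) {
  cat(sprintf("<lfp_pipeline> %s: %s (%s), k = %d PCs, test accuracy %.3f\n",
              x$pass, x$family, as.character(x$parameter), x$projection$k,
              x$metrics$accuracy))
  invisible(x)
}

#' Classify new segments with a trained pipeline
#'
#' Applies the training-time projection (never refit) and the fitted
#' classifier to new feature rows.
#'
#' @param object An `lfp_pipeline`.
#' @param newdata Feature tibble containing the 17 feature columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.lfp_pipeline <- function(object, newdata, ...) {
  predict(object$model, predict(object$projection, newdata))
}

#' Reproducibility manifest of a trained pipeline
#'
#' A plain-text account of everything needed to reproduce a fit: seed,
#' component count, CV accuracy tables, chosen family/parameter and
#' held-out metrics. Byte-identical across runs with identical inputs and
#' seed.
#'
#' @param pipeline An `lfp_pipeline`.
#' @return Character vector of manifest lines.
#' @export
pipeline_manifest <- function(pipeline) {
  stopifnot(inherits(pipeline, "lfp_pipeline"))
  m <- pipeline$metrics
  c(sprintf("pass: %s", pipeline$pass),
    sprintf("seed: %d", pipeline$seed),
    sprintf("n_segments: %d", pipeline$n),
    sprintf("pca_scaled: %s", pipeline$projection$scaled),
    sprintf("pca_threshold: %g", pipeline$projection$var_threshold),
    sprintf("pca_k: %d", pipeline$projection$k),
    sprintf("selection: %s", paste(sprintf("%s(%s)=%.6f",
      pipeline$selection$family, pipeline$selection$standard,
      pipeline$selection$cv_accuracy), collapse = " ")),
    sprintf("family: %s", pipeline$family),
    sprintf("tuning: %s", paste(sprintf("%s=%.6f",
      pipeline$tuning$parameter, pipeline$tuning$cv_accuracy),
      collapse = " ")),
    sprintf("parameter: %s", as.character(pipeline$parameter)),
    sprintf("test: tp=%d fp=%d tn=%d fn=%d acc=%.6f sens=%.6f spec=%.6f",
            m$tp, m$fp, m$tn, m$fn, m$accuracy, m$sensitivity,
            m$specificity))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the feature ranking of a fitted pipeline
#'
#' @param x An `lfp_pipeline`.
#' @param ... Unused.
#' @return The ranking tibble (`feature`, `criterion`, `rank`).
#' @export
tidy.lfp_pipeline <- function(x, ...) x$ranking

#' One-row summary of a fitted pipeline
#'
#' @param x An `lfp_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble: pass, chosen family and parameter, number of
#'   retained components and held-out metrics.
#' @export
glance.lfp_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(pass = x$pass, family = x$family,
                   parameter = as.character(x$parameter),
                   k = x$projection$k, n = x$n, seed = x$seed),
    x$metrics
  )
}
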