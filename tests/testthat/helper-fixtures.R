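# small simulated fixtures shared across test files; built once per session

.fixture_env <- new.env(parent = emptyenv())

# 30-s single-survey bilateral session: 6 five-second windows per channel
small_config <- function() {
  synth_config(n_surveys = 1, survey_duration_s = 30)
}

small_session <- function() {
  if (is.null(.fixture_env$session)) {
    .fixture_env$session <- simulate_session(small_config(), seed = 42)
  }
  .fixture_env$session
}

small_features <- function() {
  if (is.null(.fixture_env$features)) {
    s <- small_session()
    .fixture_env$features <- extract_features(segment_session(s), s$fs)
  }
  .fixture_env$features
}

# a trained Pass2 pipeline on the small fixture
small_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    labelled <- dplyr::inner_join(small_features(),
                                  training_locations("Pass2"),
                                  by = c("label", "hemisphere"))
    .fixture_env$pipeline <- train_pass_classifier(labelled, "Pass2", seed = 42)
  }
  .fixture_env$pipeline
}

# deterministic two-class score matrix that is linearly separable in PC1
separable_scores <- function(n_per_class = 30, p = 3, gap = 6, seed = 11) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
    x[, 1] <- x[, 1] + rep(c(0, gap), each = n_per_class)
    list(x = tibble::as_tibble(as.data.frame(x)),
         y = rep(c(0L, 1L), each = n_per_class))
  })
}
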