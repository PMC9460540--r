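# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Default involvement-dependent effect sizes
#'
#' The generator scales gamma and alpha oscillation amplitudes and the
#' cross-channel coupling weight with the involvement grade of a channel's
#' spatial location. Gains are non-decreasing in grade rank, encoding the
#' working hypothesis that gamma (and alpha) activity and in-target phase
#' coupling increase with target involvement.
#'
#' @return A tibble with columns `grade`, `gamma_gain`, `alpha_gain`,
#'   `coupling`.
#' @export
default_involvement_effects <- function() {
  tibble::tibble(
    grade      = c("-", "+", "++", "+++"),
    gamma_gain = c(1.0, 1.5, 2.1, 2.8),
    alpha_gain = c(1.0, 1.25, 1.55, 1.9),
    coupling   = c(0.2, 0.4, 0.6, 0.8)
  )
}

#' Synthetic LFP session configuration
#'
#' Configures the surrogate LFP generator. Each bipolar channel is the sum
#' of (i) a 1/f^a background, (ii) band-limited alpha (8-12 Hz) and gamma
#' (30-100 Hz) oscillations whose amplitudes scale with the channel
#' location's involvement grade, and (iii) a hemisphere-shared narrow-band
#' (9-11 Hz) component injected with a per-channel phase lag and a mixing
#' weight set by the grade's coupling strength. All amplitudes are RMS
#' values in microvolts.
#'
#' The default recording layout follows the reference acquisition protocol:
#' 11 surveys of 21 s (231 s in total) per pass and hemisphere at 250 Hz.
#' With `layout = "pooled"` (default) the 231 s are emitted as one
#' continuous survey block, so that 5-s segmentation yields 46 windows per
#' channel; `layout = "split"` keeps the 11 blocks separate (44 windows).
#'
#' @param fs Sampling rate in Hz.
#' @param n_surveys Number of survey blocks.
#' @param survey_duration_s Duration of each survey in seconds.
#' @param layout `"pooled"` (single continuous block) or `"split"`.
#' @param noise_exponent Spectral slope `a` of the 1/f^a background.
#' @param background_rms,alpha_rms,gamma_rms,shared_rms Base RMS amplitudes
#'   (microvolts) of the background and of the oscillatory components,
#'   before grade-dependent gains.
#' @param involvement_effects Gains per grade; see
#'   [default_involvement_effects()].
#' @param shared_band Passband (Hz) of the shared coupled component.
#' @param shared_lag_s Per-channel-index phase-lag increment of the shared
#'   component, in seconds.
#' @param seed Default seed used by [simulate_session()] when none is given.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 250, n_surveys = 11, survey_duration_s = 21,
                         layout = c("pooled", "split"),
                         noise_exponent = 1,
                         background_rms = 5, alpha_rms = 2, gamma_rms = 1.5,
                         shared_rms = 1.5,
                         involvement_effects = default_involvement_effects(),
                         shared_band = c(9, 11), shared_lag_s = 0.02,
                         seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(fs > 0, n_surveys >= 1, survey_duration_s > 0)
  if (fs <= 2 * 100) {
    stop("`fs` must exceed twice the highest synthesized frequency (100 Hz)")
  }
  eff <- tibble::as_tibble(involvement_effects)
  req <- c("grade", "gamma_gain", "alpha_gain", "coupling")
  if (!all(req %in% names(eff))) {
    stop("involvement_effects must have columns: ", paste(req, collapse = ", "))
  }
  ord <- order(grade_rank(eff$grade))
  for (col in c("gamma_gain", "alpha_gain", "coupling")) {
    if (is.unsorted(eff[[col]][ord])) {
      stop("`", col, "` must be non-decreasing in grade rank")
    }
  }
  structure(
    list(fs = fs, n_surveys = as.integer(n_surveys),
         survey_duration_s = survey_duration_s, layout = layout,
         noise_exponent = noise_exponent, background_rms = background_rms,
         alpha_rms = alpha_rms, gamma_rms = gamma_rms,
         shared_rms = shared_rms, involvement_effects = eff,
         shared_band = shared_band, shared_lag_s = shared_lag_s,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f^a noise of length n, unit RMS, via spectral shaping of white noise
pink_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1e-12, seq_len(n - 1))            # kill DC, keep symmetry via index
  f <- pmin(f, n - f)                       # two-sided frequency index
  f[1L] <- Inf                              # zero out DC
  shaped <- X / f^(exponent / 2)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited unit-RMS noise
narrowband_noise <- function(n, band, fs) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0L) x else c(x[(n - k + 1L):n], x[1L:(n - k)])
}

#' Generate a synthetic bilateral LFP session
#'
#' Produces a 12-channel [lfp_session()] (6 bipolar channels per
#' hemisphere, 3 per pass) with the location-dependent spectral and
#' coupling structure described in [synth_config()]. Fully reproducible
#' from the seed.
#'
#' @param config A [synth_config()].
#' @param involvement Involvement tibble (see [default_involvement()]);
#'   must grade all 12 (label, hemisphere) locations.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An [lfp_session()].
#' @examples
#' s <- simulate_session(synth_config(n_surveys = 1, survey_duration_s = 10), seed = 7)
#' s
#' @export
simulate_session <- function(config = synth_config(),
                             involvement = default_involvement(),
                             seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  locs <- lead_locations(involvement)   # validates 12-location coverage
  n <- round(config$n_surveys * config$survey_duration_s * config$fs)
  survey_starts <- if (config$layout == "pooled") 1L else {
    1L + (seq_len(config$n_surveys) - 1L) *
      round(config$survey_duration_s * config$fs)
  }
  eff <- config$involvement_effects
  map <- .pair_location_map()
  lag_samp <- round(config$shared_lag_s * config$fs)

  channels <- with_seed_(seed, {
    purrr::map_dfr(c("Left", "Right"), function(hemi) {
      shared <- narrowband_noise(n, config$shared_band, config$fs)
      purrr::map_dfr(seq_len(nrow(map)), function(i) {
        pair <- map$pair[i]
        loc <- locs[locs$pair == pair & locs$hemisphere == hemi, ]
        g <- eff[match(loc$grade, eff$grade), ]
        x <- config$background_rms * pink_noise(n, config$noise_exponent) +
          config$alpha_rms * g$alpha_gain * narrowband_noise(n, c(8, 12), config$fs) +
          config$gamma_rms * g$gamma_gain * narrowband_noise(n, c(30, 100), config$fs) +
          config$shared_rms * g$coupling *
            circular_shift(shared, (i - 1L) * lag_samp)
        tibble::tibble(hemisphere = hemi, pair = pair, samples = list(x))
      })
    })
  })
  lfp_session(channels, fs = config$fs, survey_starts = survey_starts,
              metadata = list(generator = "lfptarget synthetic surrogate",
                              seed = as.character(seed)))
}

#' Training locations of each pass classifier
#'
#' Each pass classifier is trained to separate the location completely
#' inserted in the target (class 1, in-target) from the location completely
#' outside it (class 0, off-target) under the default grading: D-Right vs
#' B-Left for Pass1, E-Right vs A-Left for Pass2.
#'
#' @param pass `"Pass1"` or `"Pass2"`.
#' @return A tibble with columns `label`, `hemisphere`, `class`.
#' @export
training_locations <- function(pass = c("Pass1", "Pass2")) {
  pass <- match.arg(pass)
  if (pass == "Pass1") {
    tibble::tibble(label = c("D", "B"), hemisphere = c("Right", "Left"),
                   class = c(1L, 0L))
  } else {
    tibble::tibble(label = c("E", "A"), hemisphere = c("Right", "Left"),
                   class = c(1L, 0L))
  }
}

#' Generate a labelled two-class segment set for one pass
#'
#' Simulates a session, segments it, and returns only the segments of the
#' two training locations of the requested pass, labelled with `class`
#' 1 (in-target) / 0 (off-target). With the default 231-s pooled layout this
#' yields 46 segments per class.
#'
#' @inheritParams simulate_session
#' @param pass `"Pass1"` or `"Pass2"`.
#' @param window_s Segment length in seconds.
#' @return A segment tibble (see [segment_session()]) with `label` and
#'   `class` columns added.
#' @export
simulate_labelled_dataset <- function(pass = c("Pass1", "Pass2"),
                                      config = synth_config(),
                                      involvement = default_involvement(),
                                      seed = config$seed, window_s = 5) {
  pass <- match.arg(pass)
  session <- simulate_session(config, involvement, seed)
  segs <- segment_session(session, window_s)
  map <- .pair_location_map()
  segs$label <- map$label[match(segs$pair, map$pair)]
  dplyr::inner_join(segs, training_locations(pass),
                    by = c("label", "hemisphere"))
}
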