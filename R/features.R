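#' Frequency band definitions
#'
#' Canonical EEG/LFP bands used for the spectral features: delta 1-3 Hz,
#' theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz, gamma 30-100 Hz. All bands
#' are configurable; band edges are inclusive at the PSD bin level.
#'
#' @param gamma_hi Upper edge of the gamma band in Hz.
#' @return A tibble with columns `band`, `lo`, `hi`.
#' @export
band_definitions <- function(gamma_hi = 100) {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(1, 4, 8, 13, 30),
    hi   = c(3, 7, 12, 30, gamma_hi)
  )
}

# canonical ordering of the 17 per-segment features
feature_names <- function() {
  c("var", "skew", "kurt", "md",
    "bpd", "bpt", "bpa", "bpb", "bpg",
    "am", "mp", "max", "min",
    "crosscorr", "coh", "plv", "pli")
}

# ---- Welch spectral machinery -----------------------------------------------

# Hann-windowed overlapping FFT segments of a signal.
# Returns complex matrix (freq bins x segments) plus the normalization
# needed for a one-sided power spectral density in units^2/Hz.
welch_fft <- function(x, fs, window_s = 1, overlap = 0.5) {
  n <- length(x)
  nwin <- round(window_s * fs)
  if (n < nwin) stop("segment shorter than one PSD window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  segs <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * w,
                 numeric(nwin))
  F <- stats::mvfft(segs)
  nf <- nwin %/% 2L + 1L
  list(F = F[seq_len(nf), , drop = FALSE],
       freq = (seq_len(nf) - 1L) * fs / nwin,
       scale = 1 / (fs * sum(w^2)),
       nwin = nwin)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann windows (default 1 s, 50%
#' overlap). The one-sided density integrates (sum times bin width) to the
#' signal mean-square power: a unit-amplitude sinusoid carries 0.5 units^2.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s PSD window length in seconds.
#' @param overlap Fractional window overlap.
#' @return A tibble with columns `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  wf <- welch_fft(x, fs, window_s, overlap)
  p <- rowMeans(Mod(wf$F)^2) * wf$scale
  # one-sided: double all bins except DC (and Nyquist when nwin is even)
  dbl <- rep(2, length(p))
  dbl[1L] <- 1
  if (wf$nwin %% 2L == 0L) dbl[length(dbl)] <- 1
  tibble::tibble(freq = wf$freq, psd = p * dbl)
}

#' Band powers from a PSD
#'
#' Integrates a one-sided PSD over each band (inclusive bin selection
#' `lo <= f <= hi`), returning average band power in units^2.
#'
#' @param psd A tibble from [welch_psd()].
#' @param bands A tibble from [band_definitions()].
#' @return Named numeric vector, one value per band.
#' @export
band_powers <- function(psd, bands = band_definitions()) {
  df <- diff(psd$freq[1:2])
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freq >= bands$lo[i] & psd$freq <= bands$hi[i]
    sum(psd$psd[sel]) * df
  }, numeric(1))
  names(out) <- bands$band
  out
}

# ---- univariate features ----------------------------------------------------

#' Statistical features of a segment
#'
#' Sample variance, skewness (standardized third central moment), kurtosis
#' (standardized fourth central moment, non-excess convention: a Gaussian
#' scores 3) and median. For a constant segment the standardized moments
#' are undefined; they are returned as 0 and the row is flagged degenerate.
#'
#' @param x Numeric segment (length >= 2).
#' @return A one-row tibble: `var`, `skew`, `kurt`, `md`, `degenerate`.
#' @export
statistical_features <- function(x) {
  stopifnot(length(x) >= 2L)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  degenerate <- m2 == 0
  if (degenerate) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  }
  tibble::tibble(var = stats::var(x), skew = skew, kurt = kurt,
                 md = stats::median(x), degenerate = degenerate)
}

#' Morphological features of a segment
#'
#' Absolute mean `am`, mean peak amplitude `mp` (mean of `|x|` at strict
#' local maxima; for a monotone segment with no interior maximum, `mp`
#' falls back to the global maximum), and the sample extremes.
#'
#' @param x Numeric segment (length >= 3).
#' @return A one-row tibble: `am`, `mp`, `max`, `min`.
#' @export
morphological_features <- function(x) {
  stopifnot(length(x) >= 3L)
  n <- length(x)
  interior <- 2:(n - 1L)
  is_peak <- x[interior] > x[interior - 1L] & x[interior] > x[interior + 1L]
  mp <- if (any(is_peak)) mean(abs(x[interior][is_peak])) else max(x)
  tibble::tibble(am = mean(abs(x)), mp = mp, max = max(x), min = min(x))
}

#' Spectral band-power features of a segment
#'
#' @inheritParams welch_psd
#' @param bands A tibble from [band_definitions()].
#' @return A one-row tibble: `bpd`, `bpt`, `bpa`, `bpb`, `bpg` (units^2).
#' @export
spectral_features <- function(x, fs, bands = band_definitions(),
                              window_s = 1, overlap = 0.5) {
  if (any(bands$hi > fs / 2)) {
    stop("band extends above the Nyquist frequency ", fs / 2, " Hz")
  }
  bp <- band_powers(welch_psd(x, fs, window_s, overlap), bands)
  tibble::tibble(bpd = bp[["delta"]], bpt = bp[["theta"]], bpa = bp[["alpha"]],
                 bpb = bp[["beta"]], bpg = bp[["gamma"]])
}

# max |normalized cross-correlation| over lags -lag_max..lag_max, computed in
# the frequency domain; matches stats::ccf's normalization (1/n covariances)
ccf_max <- function(x, y, lag_max) {
  n <- length(x)
  a <- x - mean(x)
  b <- y - mean(y)
  denom <- n * sqrt(mean(a^2) * mean(b^2))
  if (denom == 0) return(0)
  L <- stats::nextn(n + lag_max, c(2, 3, 5))
  A <- stats::fft(c(a, numeric(L - n)))
  B <- stats::fft(c(b, numeric(L - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / L
  r <- c(cc[(L - lag_max + 1L):L], cc[seq_len(lag_max + 1L)]) / denom
  min(max(abs(r)), 1)
}

# ---- phase machinery --------------------------------------------------------

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Band-passes the signal (zero-phase Butterworth, default 1-100 Hz) and
#' returns the phase of its analytic signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band Passband in Hz; use `NULL` to skip filtering.
#' @return Phase in radians, same length as `x`.
#' @export
instantaneous_phase <- function(x, fs, band = c(1, 100)) {
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  Arg(analytic_signal(x))
}

#' Pairwise connectivity metrics
#'
#' Symmetric similarity weights between two time-aligned segments:
#' * `crosscorr`: maximum absolute normalized cross-correlation over lags
#'   up to `max_lag_s`;
#' * `coh`: magnitude-squared coherence (Welch estimate) averaged over
#'   `coh_range`;
#' * `plv`: phase locking value, the modulus of the mean unit phasor of the
#'   instantaneous phase difference;
#' * `pli`: phase lag index, `|mean(sign(sin(phase difference)))|` — exact
#'   zero-lag differences contribute 0, so volume-conducted (zero-lag)
#'   synchrony is discounted.
#'
#' All weights lie in [0, 1].
#'
#' @param x,y Equal-length numeric segments.
#' @param fs Sampling rate in Hz.
#' @param metric One of `"crosscorr"`, `"coh"`, `"plv"`, `"pli"`.
#' @param max_lag_s Cross-correlation lag bound in seconds.
#' @param coh_range Frequency range (Hz) over which coherence is averaged.
#' @param phase_band Passband used for phase estimation.
#' @param phases Optional precomputed list of the two phase vectors (used
#'   internally to avoid re-filtering).
#' @return A scalar weight in [0, 1].
#' @export
connectivity_weight <- function(x, y, fs,
                                metric = c("crosscorr", "coh", "plv", "pli"),
                                max_lag_s = 1, coh_range = c(1, 100),
                                phase_band = c(1, 100), phases = NULL) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("segments must have equal length")
  switch(metric,
    crosscorr = {
      lag_max <- min(round(max_lag_s * fs), length(x) - 1L)
      ccf_max(x, y, lag_max)
    },
    coh = {
      wx <- welch_fft(x, fs)
      wy <- welch_fft(y, fs)
      sxx <- rowMeans(Mod(wx$F)^2)
      syy <- rowMeans(Mod(wy$F)^2)
      sxy <- rowMeans(wx$F * Conj(wy$F))
      sel <- wx$freq >= coh_range[1] & wx$freq <= coh_range[2] &
        sxx > 0 & syy > 0
      mean(Mod(sxy[sel])^2 / (sxx[sel] * syy[sel]))
    },
    plv = ,
    pli = {
      if (is.null(phases)) {
        phases <- list(instantaneous_phase(x, fs, phase_band),
                       instantaneous_phase(y, fs, phase_band))
      }
      dphi <- phases[[1L]] - phases[[2L]]
      if (metric == "plv") min(Mod(mean(exp(1i * dphi))), 1)
      else abs(mean(sign(sin(dphi))))
    }
  )
}

#' Connectivity adjacency matrix of simultaneously recorded channels
#'
#' Builds the weighted, symmetric, zero-diagonal adjacency matrix of one
#' connectivity metric across a set of time-aligned segments (the three
#' same-pass, same-hemisphere channels of one analysis window).
#'
#' @param segments Named list of equal-length numeric segments.
#' @inheritParams connectivity_weight
#' @return A symmetric numeric matrix with zero diagonal and dimnames from
#'   `names(segments)`.
#' @export
connectivity_adjacency <- function(segments, fs,
                                   metric = c("crosscorr", "coh", "plv", "pli"),
                                   max_lag_s = 1, coh_range = c(1, 100),
                                   phase_band = c(1, 100)) {
  metric <- match.arg(metric)
  m <- length(segments)
  if (length(unique(lengths(segments))) != 1L) {
    stop("all segments must have equal length")
  }
  phases <- if (metric %in% c("plv", "pli")) {
    lapply(segments, instantaneous_phase, fs = fs, band = phase_band)
  } else NULL
  adj <- matrix(0, m, m, dimnames = list(names(segments), names(segments)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      adj[i, j] <- adj[j, i] <- connectivity_weight(
        segments[[i]], segments[[j]], fs, metric,
        max_lag_s = max_lag_s, coh_range = coh_range,
        phases = if (!is.null(phases)) list(phases[[i]], phases[[j]]))
    }
  }
  adj
}

#' Node strength
#'
#' Sum of the edge weights incident to each node of a weighted adjacency
#' matrix (the diagonal is ignored).
#'
#' @param adj Symmetric numeric adjacency matrix.
#' @return Named numeric vector of node strengths.
#' @export
node_strength <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  a <- adj
  diag(a) <- 0
  rowSums(a)
}

# ---- full extraction --------------------------------------------------------

#' Extract the 17-feature description of every segment
#'
#' For each (hemisphere, pass, window) group of three simultaneous
#' channels, computes per-channel statistical (`var`, `skew`, `kurt`,
#' `md`), spectral (`bpd`, `bpt`, `bpa`, `bpb`, `bpg`), morphological
#' (`am`, `mp`, `max`, `min`) features, and the channel's node strength in
#' each of the four connectivity graphs (`crosscorr`, `coh`, `plv`,
#' `pli`). Groups that do not contain exactly the three channels of a pass
#' are flagged incomplete and excluded with a warning.
#'
#' @param segments A segment tibble from [segment_session()].
#' @param fs Sampling rate in Hz.
#' @param bands Band definitions for the spectral features.
#' @param window_s,overlap Welch PSD parameters.
#' @param max_lag_s,coh_range,phase_band Connectivity parameters; see
#'   [connectivity_weight()].
#' @return A tibble with one row per segment: identifiers (`hemisphere`,
#'   `pass`, `pair`, `label`, `survey`, `window`), the 17 feature columns
#'   and a `degenerate` quality flag.
#' @export
extract_features <- function(segments, fs, bands = band_definitions(),
                             window_s = 1, overlap = 0.5,
                             max_lag_s = 1, coh_range = c(1, 100),
                             phase_band = c(1, 100)) {
  stopifnot(is.data.frame(segments))
  map <- .pair_location_map()
  segments <- tibble::as_tibble(segments)
  segments$label <- map$label[match(segments$pair, map$pair)]
  groups <- dplyr::group_split(
    dplyr::group_by(segments, .data$hemisphere, .data$pass, .data$window))
  if (any(bands$hi > fs / 2)) {
    stop("band extends above the Nyquist frequency ", fs / 2, " Hz")
  }
  n_expected <- 3L
  dropped <- 0L
  rows <- purrr::map(groups, function(g) {
    if (nrow(g) != n_expected || anyDuplicated(g$pair)) {
      dropped <<- dropped + nrow(g)
      return(NULL)
    }
    segs <- g$samples
    names(segs) <- g$pair
    # shared intermediates: one Welch decomposition and one band-limited
    # phase estimate per channel, reused by the spectral features and by
    # all pairwise metrics (equivalent to calling connectivity_adjacency
    # metric by metric, but without recomputation)
    wf <- lapply(segs, welch_fft, fs = fs, window_s = window_s,
                 overlap = overlap)
    phases <- lapply(segs, instantaneous_phase, fs = fs, band = phase_band)
    uni <- purrr::map_dfr(seq_along(segs), function(i) {
      x <- segs[[i]]
      w <- wf[[i]]
      p <- rowMeans(Mod(w$F)^2) * w$scale
      dbl <- rep(2, length(p))
      dbl[1L] <- 1
      if (w$nwin %% 2L == 0L) dbl[length(dbl)] <- 1
      bp <- band_powers(tibble::tibble(freq = w$freq, psd = p * dbl), bands)
      dplyr::bind_cols(
        statistical_features(x),
        tibble::tibble(bpd = bp[["delta"]], bpt = bp[["theta"]],
                       bpa = bp[["alpha"]], bpb = bp[["beta"]],
                       bpg = bp[["gamma"]]),
        morphological_features(x)
      )
    })
    adj <- list(crosscorr = matrix(0, 3, 3), coh = matrix(0, 3, 3),
                plv = matrix(0, 3, 3), pli = matrix(0, 3, 3))
    lag_max <- min(round(max_lag_s * fs), length(segs[[1L]]) - 1L)
    for (i in 1:2) for (j in (i + 1L):3) {
      adj$crosscorr[i, j] <- adj$crosscorr[j, i] <-
        ccf_max(segs[[i]], segs[[j]], lag_max)
      sxx <- rowMeans(Mod(wf[[i]]$F)^2)
      syy <- rowMeans(Mod(wf[[j]]$F)^2)
      sxy <- rowMeans(wf[[i]]$F * Conj(wf[[j]]$F))
      sel <- wf[[i]]$freq >= coh_range[1] & wf[[i]]$freq <= coh_range[2] &
        sxx > 0 & syy > 0
      adj$coh[i, j] <- adj$coh[j, i] <-
        mean(Mod(sxy[sel])^2 / (sxx[sel] * syy[sel]))
      dphi <- phases[[i]] - phases[[j]]
      adj$plv[i, j] <- adj$plv[j, i] <- min(Mod(mean(exp(1i * dphi))), 1)
      adj$pli[i, j] <- adj$pli[j, i] <- abs(mean(sign(sin(dphi))))
    }
    strengths <- lapply(adj, node_strength)
    dplyr::bind_cols(
      dplyr::select(g, -"samples"),
      uni[c("var", "skew", "kurt", "md",
            "bpd", "bpt", "bpa", "bpb", "bpg",
            "am", "mp", "max", "min")],
      tibble::as_tibble(strengths),
      uni["degenerate"]
    )
  })
  if (dropped > 0L) {
    warning(dropped, " segment(s) excluded: incomplete channel groups")
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$hemisphere, .data$pass, .data$window, .data$pair)
}
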