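#' LFP recording session container
#'
#' Holds a multichannel time-domain LFP recording: a sampling rate, a set of
#' bipolar channels (each a numeric sample vector in microvolts) and the
#' sample indices at which the constituent survey blocks start. Channels are
#' stored tidily as one tibble row per channel with a `samples` list-column.
#'
#' @param channels A tibble with columns `hemisphere`, `pair` and `samples`
#'   (list of equal-length numeric vectors). A `pass` column is derived from
#'   the pair if absent.
#' @param fs Sampling frequency in Hz.
#' @param survey_starts 1-based sample indices at which surveys begin
#'   (default: a single survey spanning the whole recording).
#' @param metadata Named list of free-form provenance strings.
#' @return An object of class `lfp_session`.
#' @export
lfp_session <- function(channels, fs, survey_starts = 1L, metadata = list()) {
  stopifnot(is.data.frame(channels), is.numeric(fs), length(fs) == 1L, fs > 0)
  channels <- tibble::as_tibble(channels)
  req <- c("hemisphere", "pair", "samples")
  if (!all(req %in% names(channels))) {
    stop("`channels` must have columns: ", paste(req, collapse = ", "))
  }
  map <- .pair_location_map()
  idx <- match(channels$pair, map$pair)
  if (anyNA(idx)) {
    stop("unknown pair label(s): ",
         paste(unique(channels$pair[is.na(idx)]), collapse = ", "),
         " (valid: ", paste(map$pair, collapse = ", "), ")")
  }
  if (!("pass" %in% names(channels))) channels$pass <- map$pass[idx]
  if (!all(channels$hemisphere %in% c("Left", "Right"))) {
    stop("hemisphere must be 'Left' or 'Right'")
  }
  key <- paste(channels$hemisphere, channels$pair)
  if (anyDuplicated(key)) stop("duplicate channel labels: ",
                               paste(key[duplicated(key)], collapse = ", "))
  lens <- lengths(channels$samples)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have the same length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  n <- lens[[1L]]
  survey_starts <- as.integer(survey_starts)
  if (is.unsorted(survey_starts, strictly = TRUE) ||
      survey_starts[1L] != 1L || any(survey_starts > n)) {
    stop("`survey_starts` must be strictly increasing, start at 1 and lie within the recording")
  }
  channels <- dplyr::select(channels, "hemisphere", "pass", "pair", "samples")
  structure(
    list(fs = fs, n_samples = n, survey_starts = survey_starts,
         channels = channels, metadata = metadata),
    class = "lfp_session"
  )
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf(
    "<lfp_session> %d channels x %d samples (%.1f s @ %g Hz), %d survey(s)\n",
    nrow(x$channels), x$n_samples, x$n_samples / x$fs, x$fs,
    length(x$survey_starts)))
  print(dplyr::count(x$channels, .data$hemisphere, .data$pass))
  invisible(x)
}

#' Survey durations of a session, in samples
#' @param session An [lfp_session()].
#' @return Integer vector, one entry per survey.
#' @export
survey_lengths <- function(session) {
  stopifnot(inherits(session, "lfp_session"))
  diff(c(session$survey_starts, session$n_samples + 1L))
}

#' Write / read a session file
#'
#' Sessions are exchanged as a plain-text format: a tab-separated header
#' (`fs`, `n_samples`, `survey_starts`, optional `meta` lines) followed by
#' one `channel` declaration line and one whitespace-separated sample line
#' per channel. Samples are written at full double precision so that
#' `read_session(write_session(x))` reproduces `x` exactly.
#'
#' @param session An [lfp_session()].
#' @param path File path.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns an [lfp_session()].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "lfp_session"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("lfp_session_v1", con)
  writeLines(sprintf("fs\t%.17g", session$fs), con)
  writeLines(sprintf("n_samples\t%d", session$n_samples), con)
  writeLines(paste0("survey_starts\t",
                    paste(session$survey_starts, collapse = " ")), con)
  for (k in names(session$metadata)) {
    writeLines(sprintf("meta\t%s\t%s", k, as.character(session$metadata[[k]])), con)
  }
  for (i in seq_len(nrow(session$channels))) {
    ch <- session$channels[i, ]
    writeLines(sprintf("channel\t%s\t%s\t%s", ch$hemisphere, ch$pair, ch$pass), con)
    writeLines(paste(sprintf("%.17g", ch$samples[[1L]]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "lfp_session_v1") {
    stop("not an lfp_session_v1 file: ", path)
  }
  fs <- NA_real_
  n_samples <- NA_integer_
  survey_starts <- 1L
  metadata <- list()
  hemi <- character()
  pair <- character()
  samples <- list()
  i <- 2L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    key <- f[1L]
    if (key == "fs") {
      fs <- as.numeric(f[2L])
    } else if (key == "n_samples") {
      n_samples <- as.integer(f[2L])
    } else if (key == "survey_starts") {
      survey_starts <- as.integer(strsplit(f[2L], " ", fixed = TRUE)[[1L]])
    } else if (key == "meta") {
      metadata[[f[2L]]] <- f[3L]
    } else if (key == "channel") {
      if (length(f) < 3L) stop(sprintf("line %d: malformed channel declaration", i))
      if (i + 1L > length(lines)) stop(sprintf("line %d: channel without sample line", i))
      x <- as.numeric(strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]])
      if (anyNA(x)) stop(sprintf("line %d: non-numeric sample values", i + 1L))
      hemi <- c(hemi, f[2L])
      pair <- c(pair, f[3L])
      samples <- c(samples, list(x))
      i <- i + 1L
    } else if (nzchar(trimws(lines[i]))) {
      stop(sprintf("line %d: unknown record type '%s'", i, key))
    }
    i <- i + 1L
  }
  if (is.na(fs)) stop("session file is missing the required 'fs' header: ", path)
  if (!is.na(n_samples) && any(lengths(samples) != n_samples)) {
    stop("channel length disagrees with the n_samples header")
  }
  lfp_session(tibble::tibble(hemisphere = hemi, pair = pair, samples = samples),
              fs = fs, survey_starts = survey_starts, metadata = metadata)
}

#' Cut a session into fixed-length analysis segments
#'
#' Each channel of each survey is cut into consecutive non-overlapping
#' windows of `window_s` seconds, taken from the start of the survey; a
#' trailing remainder shorter than one window is discarded. Windows never
#' straddle survey boundaries (surveys are separate recordings). With the
#' default pooled layout of 231 s in a single survey, 5-s windows yield 46
#' segments per channel.
#'
#' @param session An [lfp_session()].
#' @param window_s Window length in seconds (default 5).
#' @return A tibble with one row per segment: `hemisphere`, `pass`, `pair`,
#'   `survey`, `window` (1-based within the whole session), and a `samples`
#'   list-column of `round(window_s * fs)` values.
#' @export
segment_session <- function(session, window_s = 5) {
  stopifnot(inherits(session, "lfp_session"), window_s > 0)
  wlen <- round(window_s * session$fs)
  slens <- survey_lengths(session)
  n_per_survey <- slens %/% wlen
  if (sum(n_per_survey) == 0L) {
    warning("window longer than every survey: no segments produced")
  }
  starts <- integer(0)
  survey_of <- integer(0)
  for (s in seq_along(slens)) {
    if (n_per_survey[s] > 0L) {
      st <- session$survey_starts[s] + (seq_len(n_per_survey[s]) - 1L) * wlen
      starts <- c(starts, st)
      survey_of <- c(survey_of, rep(s, n_per_survey[s]))
    }
  }
  purrr::map_dfr(seq_len(nrow(session$channels)), function(i) {
    ch <- session$channels[i, ]
    x <- ch$samples[[1L]]
    tibble::tibble(
      hemisphere = ch$hemisphere, pass = ch$pass, pair = ch$pair,
      survey = survey_of, window = seq_along(starts),
      samples = purrr::map(starts, function(st) x[st:(st + wlen - 1L)])
    )
  })
}
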