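#' Four-contact DBS lead model
#'
#' Describes the physical layout of a cylindrical DBS lead with equally
#' spaced ring contacts. The default corresponds to the Medtronic 3389 lead:
#' four contacts of 1.5 mm length separated by 0.5 mm gaps.
#'
#' Positions along the lead axis are measured in mm from the distal edge of
#' contact 0, increasing proximally. The quantities of interest
#' (pair midpoints and contact-to-midpoint distances) are invariant to this
#' affine choice of origin.
#'
#' @param contact_length Contact length in mm (> 0).
#' @param contact_gap Gap between adjacent contacts in mm (>= 0).
#' @param n_contacts Number of ring contacts.
#' @return An object of class `lead_model`.
#' @examples
#' lead_model()
#' contact_centers(lead_model())
#' @export
lead_model <- function(contact_length = 1.5, contact_gap = 0.5, n_contacts = 4L) {
  stopifnot(is.numeric(contact_length), length(contact_length) == 1L,
            is.numeric(contact_gap), length(contact_gap) == 1L)
  if (contact_length <= 0) stop("`contact_length` must be > 0 (mm)")
  if (contact_gap < 0) stop("`contact_gap` must be >= 0 (mm)")
  n_contacts <- as.integer(n_contacts)
  if (n_contacts < 2L) stop("`n_contacts` must be >= 2")
  structure(
    list(contact_length = contact_length, contact_gap = contact_gap,
         n_contacts = n_contacts),
    class = "lead_model"
  )
}

#' @export
print.lead_model <- function(x, ...) {
  cat(sprintf("<lead_model> %d contacts, length %.2f mm, gap %.2f mm\n",
              x$n_contacts, x$contact_length, x$contact_gap))
  invisible(x)
}

#' Axial center of a lead contact
#'
#' The center of contact `i` lies at `i * (L + g) + L / 2` mm from the distal
#' edge of contact 0, where `L` is the contact length and `g` the
#' inter-contact gap.
#'
#' @param lead A [lead_model()].
#' @param i Contact index (0-based), scalar or vector.
#' @return Position(s) along the lead axis in mm.
#' @examples
#' contact_center(lead_model(), 0) # 0.75
#' contact_center(lead_model(), 3) # 6.75
#' @export
contact_center <- function(lead = lead_model(), i) {
  stopifnot(inherits(lead, "lead_model"))
  i <- as.integer(i)
  bad <- i < 0L | i >= lead$n_contacts
  if (any(bad)) {
    stop(sprintf("contact index out of range: %s (valid range 0..%d)",
                 paste(i[bad], collapse = ", "), lead$n_contacts - 1L))
  }
  i * (lead$contact_length + lead$contact_gap) + lead$contact_length / 2
}

#' @rdname contact_center
#' @export
contact_centers <- function(lead = lead_model()) {
  contact_center(lead, seq_len(lead$n_contacts) - 1L)
}

# canonical pair -> location -> pass correspondence for the 4-contact lead
.pair_location_map <- function() {
  tibble::tibble(
    pair       = c("0-1", "0-2", "1-2", "0-3", "1-3", "2-3"),
    contact_lo = c(0L, 0L, 1L, 0L, 1L, 2L),
    contact_hi = c(1L, 2L, 2L, 3L, 3L, 3L),
    label      = c("A", "B", "C_Pass2", "C_Pass1", "D", "E"),
    pass       = c("Pass2", "Pass1", "Pass2", "Pass1", "Pass1", "Pass2")
  )
}

#' Bipolar survey montages
#'
#' The sensing mode of the neurostimulator records six bipolar channels in
#' two groups ("passes"): Pass1 uses the non-adjacent, stimulation-compatible
#' pairs 0-3, 1-3 and 0-2; Pass2 the immediately adjacent pairs 0-1, 1-2 and
#' 2-3. Together the two passes cover all `choose(4, 2) = 6` contact pairs.
#'
#' @param pass `"Pass1"`, `"Pass2"` or `"all"`.
#' @return A tibble with columns `pair`, `contact_lo`, `contact_hi`, `label`
#'   (spatial-location label A-E) and `pass`.
#' @examples
#' montage("Pass2")
#' @export
montage <- function(pass = c("all", "Pass1", "Pass2")) {
  pass <- match.arg(pass)
  m <- .pair_location_map()
  # present each pass in its conventional order (widest first for Pass1)
  order_1 <- c("0-3", "1-3", "0-2")
  order_2 <- c("0-1", "1-2", "2-3")
  m <- m[match(c(order_1, order_2), m$pair), ]
  if (pass != "all") m <- dplyr::filter(m, .data$pass == .env$pass)
  m
}

#' Midpoint and contact-to-midpoint distance of bipolar pairs
#'
#' A bipolar LFP channel is nominally localized at the midpoint between its
#' two contacts; `d` is the distance from either contact center to that
#' midpoint (half the center-to-center separation). On the default lead,
#' adjacent pairs have d = 1 mm, skip-one pairs (0-2, 1-3) d = 2 mm and the
#' widest pair (0-3) d = 3 mm.
#'
#' @param pairs A data frame with `contact_lo`/`contact_hi` columns (as
#'   returned by [montage()]), or a character vector of pair labels such as
#'   `"0-3"`.
#' @param lead A [lead_model()].
#' @return The input as a tibble with `midpoint_mm` and `d_mm` columns added.
#' @examples
#' pair_geometry(montage("Pass1"))
#' pair_geometry("0-3") # d = 3 mm on the default lead
#' @export
pair_geometry <- function(pairs = montage("all"), lead = lead_model()) {
  if (is.character(pairs)) {
    m <- .pair_location_map()
    idx <- match(pairs, m$pair)
    if (anyNA(idx)) {
      stop("unknown pair label(s): ", paste(pairs[is.na(idx)], collapse = ", "),
           " (valid: ", paste(m$pair, collapse = ", "), ")")
    }
    pairs <- m[idx, ]
  }
  stopifnot(is.data.frame(pairs),
            all(c("contact_lo", "contact_hi") %in% names(pairs)))
  if (any(pairs$contact_lo >= pairs$contact_hi)) {
    stop("bipolar pairs must satisfy contact_lo < contact_hi")
  }
  lo <- contact_center(lead, pairs$contact_lo)
  hi <- contact_center(lead, pairs$contact_hi)
  dplyr::mutate(tibble::as_tibble(pairs),
                midpoint_mm = (lo + hi) / 2,
                d_mm = (hi - lo) / 2)
}

#' Ordinal involvement grades
#'
#' Target involvement of a spatial location is graded ordinally from medical
#' imaging: `-` completely outside the target, `+` marginally in, `++`
#' partially inserted, `+++` completely inserted. `grade_rank()` maps the
#' symbols to ranks 0-3 for monotonicity analyses; the grades carry no
#' metric meaning beyond their order.
#'
#' @param grade Character vector of grades in `c("-", "+", "++", "+++")`
#'   (the Unicode minus sign is accepted and normalized).
#' @return Integer ranks 0-3.
#' @examples
#' grade_rank(c("-", "+++"))
#' @export
grade_rank <- function(grade) {
  grade <- gsub("−", "-", grade)
  levels <- c("-", "+", "++", "+++")
  r <- match(grade, levels) - 1L
  if (anyNA(r) && !anyNA(grade)) {
    stop("unknown involvement grade(s): ",
         paste(unique(grade[is.na(r)]), collapse = ", "))
  }
  r
}

#' Default involvement table
#'
#' The per-(location, hemisphere) involvement grading of the bilateral
#' ANT-DBS case the methodology was developed on, shipped as a plain-text
#' table. In that case the deepest contacts (3 left; 2 and 3 right) lie in
#' the target, so involvement increases towards location E (pair 2-3) and is
#' uniformly higher in the right hemisphere.
#'
#' @param path Optional path to a delimited involvement table with columns
#'   `label`, `hemisphere`, `grade`; defaults to the packaged table.
#' @return A tibble with columns `label`, `hemisphere`, `grade`, `grade_rank`.
#' @examples
#' default_involvement()
#' @export
default_involvement <- function(path = system.file("extdata", "involvement_default.csv",
                                                   package = "lfptarget")) {
  read_involvement(path)
}

#' @rdname default_involvement
#' @export
read_involvement <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("label", "hemisphere", "grade")
  if (!all(req %in% names(df))) {
    stop("involvement table must have columns: ", paste(req, collapse = ", "))
  }
  df$grade <- gsub("−", "-", df$grade)
  out <- tibble::as_tibble(df[req])
  out$grade_rank <- grade_rank(out$grade)
  if (anyDuplicated(paste(out$label, out$hemisphere))) {
    stop("duplicate (label, hemisphere) rows in involvement table")
  }
  out
}

#' Spatial locations of all bipolar channels
#'
#' Joins pair geometry with the involvement table, producing one row per
#' (pair, hemisphere): 12 labelled spatial locations for a bilateral
#' implant. Note that pairs 1-2 and 0-3 share the same midpoint but differ
#' in `d`, which is why the C location exists once per pass.
#'
#' @param involvement Involvement tibble (see [default_involvement()]).
#' @param lead A [lead_model()].
#' @return A tibble with columns `pair`, `label`, `pass`, `hemisphere`,
#'   `midpoint_mm`, `d_mm`, `grade`, `grade_rank`.
#' @export
lead_locations <- function(involvement = default_involvement(),
                           lead = lead_model()) {
  geo <- pair_geometry(.pair_location_map(), lead)
  out <- dplyr::inner_join(
    tidyr::crossing(geo, hemisphere = c("Left", "Right")),
    involvement,
    by = c("label", "hemisphere")
  )
  missing <- dplyr::anti_join(
    tidyr::crossing(label = geo$label, hemisphere = c("Left", "Right")),
    involvement, by = c("label", "hemisphere")
  )
  if (nrow(missing) > 0L) {
    stop("involvement table missing entries for: ",
         paste(paste0(missing$label, "/", missing$hemisphere), collapse = ", "))
  }
  dplyr::select(out, "pair", "label", "pass", "hemisphere",
                "midpoint_mm", "d_mm", "grade", "grade_rank")
}

#' Location of a single bipolar pair
#'
#' @param pair Pair label such as `"2-3"`.
#' @param hemisphere `"Left"` or `"Right"`.
#' @inheritParams lead_locations
#' @return A one-row tibble (see [lead_locations()]).
#' @examples
#' location_of("2-3", "Right")
#' @export
location_of <- function(pair, hemisphere, involvement = default_involvement(),
                        lead = lead_model()) {
  locs <- lead_locations(involvement, lead)
  out <- dplyr::filter(locs, .data$pair == .env$pair,
                       .data$hemisphere == .env$hemisphere)
  if (nrow(out) == 0L) {
    stop(sprintf("no location for pair '%s' in hemisphere '%s'",
                 pair, hemisphere))
  }
  out
}
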