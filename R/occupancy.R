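#' Nucleosome formation potential
#'
#' Boltzmann weight of placing a nucleosome dyad on DNA with deformation
#' energy `E`: `S = exp(-beta * E)`.  Energies are in the arbitrary
#' units of the step-parameter table, so `beta` is a unitless inverse
#' temperature (default 1).
#'
#' @param E deformation energy (vectorised; `NA` passes through).
#' @param beta inverse-temperature factor, positive.
#' @return formation potential in (0, 1] for nonnegative `E`.
#' @export
formation_potential <- function(E, beta = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  exp(-beta * E)
}

#' Per-base-pair occupancy track
#'
#' Lightweight container for a per-bp signal along one sequence:
#' predicted formation potential, predicted or experimental occupancy,
#' or normalized occupancy.  Undefined positions are `NA`.
#'
#' @param seq_id sequence identifier.
#' @param values numeric vector, one value per base pair.
#' @param kind one of `"potential"`, `"occupancy"`, `"normalized"`.
#' @param origin 0-based position of `values[1]` on the sequence.
#' @param metadata named list of provenance (model constants etc.).
#' @return an `occupancy_track`.
#' @export
occupancy_track <- function(seq_id, values, kind = "occupancy",
                            origin = 0L, metadata = list()) {
  kind <- match.arg(kind, c("potential", "occupancy", "normalized"))
  stopifnot(is.numeric(values))
  if (kind != "normalized" && any(values <= 0, na.rm = TRUE)) {
    stop("potential and occupancy values must be positive where defined")
  }
  structure(list(seq_id = as.character(seq_id), origin = as.integer(origin),
                 values = as.numeric(values), kind = kind,
                 metadata = metadata),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  n_def <- sum(!is.na(x$values))
  cat(sprintf("<occupancy_track> %s [%d, %d) kind=%s, %d/%d defined\n",
              x$seq_id, x$origin, x$origin + length(x$values), x$kind,
              n_def, length(x$values)))
  invisible(x)
}

# values of a track at 0-based genomic positions (NA outside)
track_values_at <- function(track, pos) {
  idx <- pos - track$origin + 1L
  idx[idx < 1L | idx > length(track$values)] <- NA_integer_
  track$values[idx]
}

#' Predicted nucleosome occupancy along a sequence
#'
#' Runs the elastic model at every dyad position with a full contact
#' window, converts energies to formation potentials `S = exp(-beta E)`,
#' and averages `S` over a sliding `smoothing_window`-bp window centred
#' at each base pair.  Near sequence ends (and next to ambiguous bases)
#' the window is truncated to the defined potentials it contains; a
#' position with no defined potential in its window is `NA`.  With
#' `full_window_only = TRUE` occupancy is reported only where all
#' `smoothing_window` potentials exist.
#'
#' @param sequence DNA string, length at least `geom$contact_len`.
#' @param table a [step_param_table()].
#' @param geom an [elastic_geometry()].
#' @param beta inverse-temperature factor.
#' @param smoothing_window odd window width `l` in bp for the occupancy
#'   average (default 51).
#' @param seq_id identifier recorded on the output track.
#' @param full_window_only require a complete window of defined
#'   potentials.
#' @return an `occupancy_track` of kind `"occupancy"` spanning the whole
#'   sequence (positions outside any window are `NA`).
#' @export
occupancy_profile <- function(sequence, table = step_param_table(),
                              geom = elastic_geometry(), beta = 1,
                              smoothing_window = 51L, seq_id = "seq",
                              full_window_only = FALSE) {
  l <- as.integer(smoothing_window)
  if (l < 1L || l %% 2L != 1L) stop("smoothing_window must be odd and >= 1")
  land <- energy_landscape(sequence, table, geom)
  L <- nchar(sequence)
  S <- rep(NA_real_, L)
  S[land$dyad + 1L] <- formation_potential(land$energy, beta)

  # windowed sums, not cumulative-sum differences: potentials span many
  # orders of magnitude and differencing long cumsums cancels them away
  h <- (l - 1L) %/% 2L
  def <- !is.na(S)
  pad <- rep(0, h)
  tot <- stats::filter(c(pad, ifelse(def, S, 0), pad), rep(1, l),
                       sides = 2)[(h + 1L):(h + L)]
  cnt <- stats::filter(c(pad, as.numeric(def), pad), rep(1, l),
                       sides = 2)[(h + 1L):(h + L)]
  cnt <- round(cnt)
  O <- ifelse(cnt > 0, tot / pmax(cnt, 1), NA_real_)
  j <- seq_len(L)
  if (full_window_only) O[cnt < l | (j - h) < 1L | (j + h) > L] <- NA_real_

  occupancy_track(seq_id, O, kind = "occupancy",
                  metadata = list(beta = beta, smoothing_window = l,
                                  alpha_total = geom$alpha_total,
                                  omega = geom$omega,
                                  contact_len = geom$contact_len))
}

#' Normalize an occupancy track to log-ratio scale
#'
#' Divides by a reference mean occupancy and takes the natural
#' logarithm, so 0 means average occupancy and positive values mean
#' enrichment.  With `reference_mean = "auto"` the mean of the defined
#' values of the track itself is used; pass a precomputed positive mean
#' to normalize several tracks against a common reference.
#'
#' @param track an `occupancy_track` of kind `"occupancy"`.
#' @param reference_mean `"auto"` or a positive number.
#' @return an `occupancy_track` of kind `"normalized"`; the reference
#'   and log base are recorded in `metadata`.
#' @export
normalize_occupancy <- function(track, reference_mean = "auto") {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$kind == "normalized") stop("track is already normalized")
  if (identical(reference_mean, "auto")) {
    reference_mean <- mean(track$values, na.rm = TRUE)
  }
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    stop("reference mean must be a positive finite number")
  }
  md <- track$metadata
  md$reference_mean <- reference_mean
  md$log_base <- "e"
  occupancy_track(track$seq_id, log(track$values / reference_mean),
                  kind = "normalized", origin = track$origin,
                  metadata = md)
}

#' Write an occupancy track as bedGraph
#'
#' Consecutive equal values are run-length collapsed into intervals;
#' `NA` positions are omitted.  Model constants from the track metadata
#' are recorded as `#`-comment header lines.
#'
#' @param track an `occupancy_track`.
#' @param path output file.
#' @param digits significant digits for values.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 8L) {
  stopifnot(inherits(track, "occupancy_track"))
  hdr <- c(sprintf("track type=bedGraph name=\"%s_%s\"",
                   track$seq_id, track$kind),
           vapply(names(track$metadata), function(k) {
             sprintf("# %s=%s", k, format(track$metadata[[k]]))
           }, ""))
  v <- track$values
  def <- !is.na(v)
  lines <- character(0)
  if (any(def)) {
    key <- ifelse(def, paste0(format(v, digits = 15L)), "NA")
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "NA"
    lines <- sprintf("%s\t%d\t%d\t%s", track$seq_id,
                     track$origin + starts[keep] - 1L,
                     track$origin + ends[keep],
                     formatC(v[starts[keep]], digits = digits,
                             format = "g"))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
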