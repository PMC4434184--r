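#' Read a coarse-resolution occupancy track
#'
#' Parses a bedGraph or wiggle (fixedStep/variableStep) file of binned
#' occupancy values, as produced by nucleosome-sequencing pipelines at
#' e.g. 10-bp resolution, into a validated bin table.  Coordinates are
#' normalized to 0-based half-open.  Unsorted input is sorted with a
#' warning; overlapping bins are an error.
#'
#' @param path input file.
#' @param format `"auto"` (from the extension), `"bedGraph"` or
#'   `"wig"`.
#' @return a `coarse_track`: data frame with columns `seq_id`, `start`,
#'   `end`, `value`, plus attribute `bin_size` (the modal bin width).
#' @export
read_coarse_track <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  has_data <- length(grep("^(#|track|browser)|^\\s*$",
                          readLines(path), invert = TRUE)) > 0L
  if (!has_data) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
    attr(out, "bin_size") <- NA_integer_
    class(out) <- c("coarse_track", "data.frame")
    return(out)
  }
  gr <- rtracklayer::import(path, format = format)
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE)
  ord <- order(out$seq_id, out$start)
  if (!identical(ord, seq_len(nrow(out)))) {
    warning("coarse track was not sorted; sorting by (seq_id, start)")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  by_seq <- split(out, out$seq_id)
  for (b in by_seq) {
    if (nrow(b) > 1L) {
      bad <- which(b$start[-1L] < b$end[-nrow(b)])
      if (length(bad)) {
        stop(sprintf("overlapping bins on %s: [%d, %d) overlaps [%d, %d)",
                     b$seq_id[1L], b$start[bad[1L]], b$end[bad[1L]],
                     b$start[bad[1L] + 1L], b$end[bad[1L] + 1L]))
      }
    }
  }
  w <- out$end - out$start
  tab <- table(w)
  attr(out, "bin_size") <- as.integer(names(tab)[which.max(tab)])
  class(out) <- c("coarse_track", "data.frame")
  out
}

#' Interpolate a coarse track to per-base-pair resolution
#'
#' Fits a cubic spline through the bin midpoints of each contiguous run
#' of bins and evaluates it at every integer base position between the
#' outermost knots of the run (no extrapolation).  Runs are broken
#' wherever consecutive bins leave a gap, so no values are bridged
#' across missing data.  A run with fewer than four knots cannot
#' support a cubic and falls back to linear interpolation with a
#' warning.
#'
#' @param track a `coarse_track` from [read_coarse_track()].
#' @param method spline boundary condition passed to [stats::spline()]:
#'   `"natural"` (zero second derivative at the ends, the default) or
#'   `"fmm"`.
#' @return named list of `occupancy_track` objects, one per `seq_id`;
#'   positions in gaps between runs are `NA`.
#' @export
spline_interpolate <- function(track, method = c("natural", "fmm")) {
  method <- match.arg(method)
  stopifnot(inherits(track, "coarse_track"))
  out <- list()
  for (sid in unique(track$seq_id)) {
    b <- track[track$seq_id == sid, , drop = FALSE]
    gap_after <- c(b$start[-1L] > b$end[-nrow(b)], FALSE)
    run <- cumsum(c(0L, utils::head(as.integer(gap_after), -1L)))
    pieces <- list()
    for (r in split(seq_len(nrow(b)), run)) {
      x <- (b$start[r] + b$end[r]) / 2
      y <- b$value[r]
      lo <- as.integer(ceiling(min(x)))
      hi <- as.integer(floor(max(x)))
      if (hi < lo) next
      xout <- lo:hi
      if (length(x) >= 4L) {
        fit <- stats::spline(x, y, xout = xout, method = method)$y
      } else {
        warning(sprintf("run of %d bins on %s: too few knots for a cubic, %s",
                        length(x), sid, "using linear interpolation"))
        fit <- stats::approx(x, y, xout = xout)$y
      }
      pieces[[length(pieces) + 1L]] <- list(lo = lo, hi = hi, fit = fit)
    }
    if (!length(pieces)) next
    origin <- pieces[[1L]]$lo
    values <- rep(NA_real_,
                  pieces[[length(pieces)]]$hi - origin + 1L)
    for (p in pieces) {
      values[(p$lo - origin + 1L):(p$hi - origin + 1L)] <- p$fit
    }
    out[[sid]] <- occupancy_track(sid, values, kind = "occupancy",
                                  origin = origin,
                                  metadata = list(source = "interpolated",
                                                  spline = method))
  }
  out
}

#' Expand a binned track to a per-base-pair occupancy track
#'
#' Assigns each bin's value to every base it covers — the inverse of
#' the run-length collapsing done by [write_bedgraph()], so a per-bp
#' track written to bedGraph round-trips through
#' [read_coarse_track()] and this function.  Uncovered positions
#' between bins are `NA`.
#'
#' @param track a `coarse_track`.
#' @param kind track kind (`"normalized"` for log-ratio values).
#' @return named list of `occupancy_track` objects, one per `seq_id`.
#' @export
track_from_bins <- function(track, kind = "occupancy") {
  stopifnot(inherits(track, "coarse_track"))
  out <- list()
  for (sid in unique(track$seq_id)) {
    b <- track[track$seq_id == sid, , drop = FALSE]
    origin <- min(b$start)
    values <- rep(NA_real_, max(b$end) - origin)
    for (k in seq_len(nrow(b))) {
      values[(b$start[k] - origin + 1L):(b$end[k] - origin)] <- b$value[k]
    }
    out[[sid]] <- occupancy_track(sid, values, kind = kind,
                                  origin = origin)
  }
  out
}
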