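#' Read stranded features with attributes
#'
#' Loads intervals from a BED file (at least 6 columns: strand is
#' required) and joins per-feature attributes from a tab-separated
#' sidecar keyed by `feature_id` (typical columns: group labels such as
#' `transcription_status` and `biotype`, and numeric attributes such as
#' `gc_content`, `identity`, `divergence`, `family_id`).  Features
#' absent from the sidecar carry `NA` attributes with a warning.
#'
#' @param bed_path BED file; the name column is the `feature_id`.
#' @param attrs_path optional attributes TSV with a `feature_id`
#'   column.
#' @return a `feature_set`: data frame with columns `seq_id`, `start`,
#'   `end` (0-based half-open), `strand`, `feature_id`, plus any
#'   attribute columns.
#' @export
read_features <- function(bed_path, attrs_path = NULL) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("all features must have a strand (+ or -)")
  }
  ids <- as.character(gr$name)
  if (anyNA(ids) || any(ids == "")) stop("all features must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate feature_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    feature_id = ids,
    stringsAsFactors = FALSE)
  bad <- out$start >= out$end
  if (any(bad)) {
    stop("malformed interval (start >= end) for feature: ",
         paste(out$feature_id[bad], collapse = ", "))
  }
  if (!is.null(attrs_path)) {
    attrs <- utils::read.delim(attrs_path, stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(attrs)) {
      stop("attributes TSV must have a feature_id column")
    }
    if (anyDuplicated(attrs$feature_id)) {
      stop("duplicate feature_id in attributes TSV")
    }
    m <- match(out$feature_id, attrs$feature_id)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " feature(s) missing from attributes TSV; ",
              "their attributes are NA")
    }
    for (col in setdiff(names(attrs), "feature_id")) {
      out[[col]] <- attrs[[col]][m]
    }
  }
  class(out) <- c("feature_set", "data.frame")
  out
}

# 0-based position of the anchor base of a feature, transcription-oriented
anchor_base <- function(features, anchor) {
  plus <- features$strand == "+"
  if (anchor == "start") {
    ifelse(plus, features$start, features$end - 1L)
  } else {
    ifelse(plus, features$end - 1L, features$start)
  }
}

#' Aggregate a per-bp track around feature anchors
#'
#' Extracts the window `[-flank, +flank]` around the transcription-
#' oriented start or end anchor of every feature and averages the
#' signal per offset (a metaprofile).  For minus-strand features the
#' anchor is mirrored and the extracted signal reversed, so offset 0 is
#' always the first (start anchor) or last (end anchor) base of the
#' feature, positive offsets point into the feature body from a start
#' anchor and away from it at an end anchor.  Positions with no defined
#' signal simply reduce the per-offset count; no imputation.
#'
#' @param tracks a single `occupancy_track` or a named list of them
#'   keyed by `seq_id`.
#' @param features a `feature_set` (see [read_features()]).
#' @param anchor `"start"` or `"end"`.
#' @param flank half-width of the window, bp.
#' @param group_by optional name of a feature column to stratify by.
#' @return data frame with columns `offset`, `group` (`"all"` when
#'   ungrouped), `mean`, `n`.
#' @export
aggregate_profile <- function(tracks, features, anchor = c("start", "end"),
                              flank = 1000L, group_by = NULL) {
  anchor <- match.arg(anchor)
  flank <- as.integer(flank)
  stopifnot(flank > 0L)
  if (inherits(tracks, "occupancy_track")) {
    tracks <- stats::setNames(list(tracks), tracks$seq_id)
  }
  offsets <- (-flank):flank
  if (nrow(features) == 0L) {
    return(data.frame(offset = integer(0), group = character(0),
                      mean = numeric(0), n = integer(0)))
  }
  a <- anchor_base(features, anchor)
  mat <- matrix(NA_real_, nrow(features), length(offsets))
  for (f in seq_len(nrow(features))) {
    tr <- tracks[[features$seq_id[f]]]
    if (is.null(tr)) next
    pos <- if (features$strand[f] == "+") a[f] + offsets else a[f] - offsets
    mat[f, ] <- track_values_at(tr, pos)
  }
  groups <- if (is.null(group_by)) rep("all", nrow(features))
            else as.character(features[[group_by]])
  res <- lapply(unique(groups), function(g) {
    sub <- mat[groups == g, , drop = FALSE]
    data.frame(offset = offsets, group = g,
               mean = suppressWarnings(colMeans(sub, na.rm = TRUE)),
               n = colSums(!is.na(sub)))
  })
  out <- do.call(rbind, res)
  out$mean[out$n == 0L] <- NA_real_
  rownames(out) <- NULL
  out
}
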