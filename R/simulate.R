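# Synthetic inputs with known ground truth: random genomes, pseudogene-like
# features flanked by nucleosome-inhibitory elements, mutated gene families,
# and noisy coarse occupancy tracks.  Everything is deterministic under an
# explicit seed so downstream recovery tests are reproducible.

sample_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

#' Simulate a random genome
#'
#' Independent bases at a target GC content, one string per chromosome.
#'
#' @param chromosome_length length of each chromosome, bp.
#' @param n_chromosomes number of chromosomes.
#' @param gc background GC fraction, in (0, 1) or the degenerate 0/1.
#' @param seed optional integer; when given, `set.seed()` is called so
#'   the same call reproduces the same genome.
#' @return named character vector of sequences (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(chromosome_length, n_chromosomes = 1L,
                            gc = 0.41, seed = NULL) {
  stopifnot(chromosome_length > 0, n_chromosomes > 0, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(
    vapply(seq_len(n_chromosomes), function(i) {
      paste(sample_bases(chromosome_length, gc), collapse = "")
    }, ""),
    paste0("chr", seq_len(n_chromosomes)))
}

replace_substr <- function(sequence, start0, text) {
  # overwrite [start0, start0 + nchar(text)) (0-based) within sequence
  paste0(substr(sequence, 1L, start0),
         text,
         substr(sequence, start0 + nchar(text) + 1L, nchar(sequence)))
}

#' Simulate features flanked by nucleosome-inhibitory elements
#'
#' Places non-overlapping stranded features on the given chromosomes and
#' writes a homopolymeric dA:dT run (a stiff, nucleosome-disfavouring
#' element under the step parameters) immediately upstream of each
#' feature's transcriptional start anchor and immediately downstream of
#' its end anchor.  "Upstream" and "downstream" follow the feature's
#' strand, so on the minus strand the elements sit at the mirror-image
#' genomic positions.  Ground-truth element coordinates are returned for
#' recovery tests.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param n_per_group named integer vector: features per
#'   `transcription_status` group, e.g.
#'   `c(transcribed = 25, nontranscribed = 25)`.
#' @param feature_length_range min/max feature length, bp (min >= 129).
#' @param element_length length of each inhibitory dA:dT run, bp.
#' @param min_gap minimum spacing between consecutive placements
#'   (feature plus elements), bp; keep at least twice the profiling
#'   flank so metaprofile windows do not overlap neighbouring elements.
#' @param seed optional integer seed.
#' @return list with `sequences` (edited), `features` (a `feature_set`
#'   with `transcription_status` and `biotype` columns) and `elements`
#'   (data frame of ground-truth element intervals with their anchor and
#'   side).
#' @export
simulate_features_with_depletion <- function(sequences,
                                             n_per_group = c(transcribed = 25L,
                                                             nontranscribed = 25L),
                                             feature_length_range = c(600L, 2000L),
                                             element_length = 150L,
                                             min_gap = 2200L,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(n_per_group) >= 1L, !is.null(names(n_per_group)),
            feature_length_range[1L] >= 129L, element_length > 0L)
  n_total <- sum(n_per_group)
  status <- sample(rep(names(n_per_group), n_per_group))
  lens <- sample(seq(feature_length_range[1L], feature_length_range[2L]),
                 n_total, replace = TRUE)
  slot <- element_length * 2L + max(lens) + min_gap
  capacity <- sum(vapply(sequences, nchar, 0L) %/% slot)
  if (capacity < n_total) {
    stop("infeasible packing: chromosomes fit at most ", capacity,
         " features at this spacing, ", n_total, " requested")
  }
  feats <- list(); elems <- list()
  f <- 0L
  for (sid in names(sequences)) {
    n_here <- min(nchar(sequences[[sid]]) %/% slot, n_total - f)
    if (n_here < 1L) next
    for (k in seq_len(n_here)) {
      f <- f + 1L
      # slot layout leaves >= min_gap between consecutive placements
      start <- (k - 1L) * slot + element_length + min_gap %/% 2L
      end <- start + lens[f]
      strand <- sample(c("+", "-"), 1L)
      # transcription-oriented flanks: upstream of the start anchor and
      # downstream of the end anchor
      if (strand == "+") {
        up <- c(start - element_length, start)
        down <- c(end, end + element_length)
      } else {
        up <- c(end, end + element_length)
        down <- c(start - element_length, start)
      }
      run <- strrep("A", element_length)
      sequences[[sid]] <- replace_substr(sequences[[sid]], up[1L], run)
      sequences[[sid]] <- replace_substr(sequences[[sid]], down[1L], run)
      feats[[f]] <- data.frame(
        seq_id = sid, start = start, end = end, strand = strand,
        feature_id = sprintf("pg%03d", f),
        transcription_status = status[f],
        biotype = sample(c("processed", "duplicated"), 1L),
        stringsAsFactors = FALSE)
      elems[[f]] <- data.frame(
        feature_id = sprintf("pg%03d", f), seq_id = sid,
        anchor = c("start", "end"), side = c("upstream", "downstream"),
        start = c(up[1L], down[1L]), end = c(up[2L], down[2L]),
        stringsAsFactors = FALSE)
    }
    if (f >= n_total) break
  }
  features <- do.call(rbind, feats)
  class(features) <- c("feature_set", "data.frame")
  list(sequences = sequences, features = features,
       elements = do.call(rbind, elems))
}

mutate_sequence <- function(parent, rate, at_bias) {
  b <- strsplit(parent, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit)) {
    for (j in which(hit)) {
      alt <- setdiff(DNA_BASES, b[j])
      w <- ifelse(alt %in% c("A", "T"), at_bias / 2, (1 - at_bias) / 2)
      b[j] <- sample(alt, 1L, prob = w)
    }
  }
  paste(b, collapse = "")
}

#' Simulate a cohort of pseudogene families
#'
#' Each family has one random parent sequence; members are independent
#' copies mutated at graded per-site rates with an AT bias, so identity
#' to the parent and member GC content decay together — the degeneration
#' pattern real processed pseudogenes show as they age.  Recorded
#' attributes are exact: `identity` is the realised fraction of matching
#' positions, `gc_content` the realised member GC, and `divergence` the
#' per-site mutation rate the member was drawn at (a proxy for
#' evolutionary distance).
#'
#' @param n_families number of families.
#' @param members_per_family members per family.
#' @param member_length sequence length, bp (>= 129).
#' @param parent_gc parent GC fraction.
#' @param max_rate members' mutation rates are evenly graded in
#'   `[0, max_rate]`.
#' @param at_bias probability that a mutation lands on A or T.
#' @param seed optional integer seed.
#' @return list with `sequences` (one per member, named by feature id)
#'   and `features` (a `feature_set` with `gc_content`, `identity`,
#'   `divergence`, `family_id`).
#' @export
simulate_family_cohort <- function(n_families = 50L, members_per_family = 20L,
                                   member_length = 400L, parent_gc = 0.55,
                                   max_rate = 0.35, at_bias = 0.85,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(member_length >= 129L, max_rate >= 0, max_rate <= 1,
            at_bias >= 0, at_bias <= 1)
  seqs <- character(0)
  rows <- list()
  rates <- seq(0, max_rate, length.out = members_per_family)
  for (fam in seq_len(n_families)) {
    parent <- paste(sample_bases(member_length, parent_gc), collapse = "")
    for (m in seq_len(members_per_family)) {
      id <- sprintf("fam%03d_m%02d", fam, m)
      child <- mutate_sequence(parent, rates[m], at_bias)
      cb <- strsplit(child, "", fixed = TRUE)[[1]]
      pb <- strsplit(parent, "", fixed = TRUE)[[1]]
      seqs[[id]] <- child
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = 0L, end = member_length, strand = "+",
        feature_id = id, family_id = sprintf("fam%03d", fam),
        gc_content = mean(cb %in% c("G", "C")),
        identity = mean(cb == pb),
        divergence = rates[m],
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  class(features) <- c("feature_set", "data.frame")
  list(sequences = seqs, features = features)
}

#' Simulate a coarse experimental occupancy track
#'
#' A mock nucleosome-sequencing signal at fixed bin resolution: constant
#' baseline plus Gaussian noise, with smooth Gaussian-shaped dips
#' painted at given genomic centres (typically the ground-truth
#' inhibitory-element centres around feature anchors).  The dips are
#' painted independently of the underlying sequence, mirroring the fact
#' that in vivo occupancy also reflects factors beyond sequence.
#'
#' @param sequences named character vector of chromosome sequences
#'   (only the lengths are used).
#' @param dip_centers optional data frame with `seq_id` and numeric
#'   `center` columns.
#' @param bin_size bin width, bp (default 10, the resolution of typical
#'   MNase tag-count profiles).
#' @param baseline baseline occupancy per bin.
#' @param noise_sd Gaussian noise standard deviation.
#' @param dip_depth depth of each dip at its centre.
#' @param dip_sd Gaussian width (sd) of each dip, bp.
#' @param seed optional integer seed.
#' @return a `coarse_track` (see [read_coarse_track()]).
#' @export
simulate_coarse_track <- function(sequences, dip_centers = NULL,
                                  bin_size = 10L, baseline = 1,
                                  noise_sd = 0.05, dip_depth = 0.5,
                                  dip_sd = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(bin_size > 0L, baseline > 0, noise_sd >= 0)
  rows <- list()
  for (sid in names(sequences)) {
    L <- nchar(sequences[[sid]])
    starts <- seq(0L, L - bin_size, by = bin_size)
    mids <- starts + bin_size / 2
    v <- baseline + stats::rnorm(length(starts), 0, noise_sd)
    if (!is.null(dip_centers)) {
      for (ctr in dip_centers$center[dip_centers$seq_id == sid]) {
        v <- v - dip_depth * exp(-0.5 * ((mids - ctr) / dip_sd)^2)
      }
    }
    rows[[sid]] <- data.frame(seq_id = sid, start = starts,
                              end = starts + bin_size, value = v,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("coarse_track", "data.frame")
  out
}

#' Write a simulated study to disk
#'
#' Emits the standard plain-text artefacts of a simulation: FASTA
#' sequences, BED6 features, an attributes TSV keyed by `feature_id`, a
#' bedGraph coarse track, and a JSON ground-truth manifest.
#'
#' @param dir output directory (created if needed).
#' @param sequences named character vector of sequences.
#' @param features a `feature_set`.
#' @param coarse_track optional `coarse_track`.
#' @param manifest list of ground-truth values to record as JSON.
#' @return named vector of the written paths, invisibly.
#' @export
write_simulation <- function(dir, sequences, features,
                             coarse_track = NULL, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             bed = file.path(dir, "features.bed"),
             attrs = file.path(dir, "features.tsv"),
             manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences),
                              paths[["fasta"]])
  bed <- data.frame(features$seq_id, features$start, features$end,
                    features$feature_id, 0L, features$strand)
  utils::write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  attr_cols <- setdiff(names(features),
                       c("seq_id", "start", "end", "strand"))
  utils::write.table(features[attr_cols], paths[["attrs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(coarse_track)) {
    paths[["bedgraph"]] <- file.path(dir, "coarse_track.bedGraph")
    lines <- sprintf("%s\t%d\t%d\t%.6g", coarse_track$seq_id,
                     coarse_track$start, coarse_track$end,
                     coarse_track$value)
    writeLines(c("track type=bedGraph name=\"coarse_occupancy\"", lines),
               paths[["bedgraph"]])
  }
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a run configuration file
#'
#' YAML key tree of pipeline parameters (geometry constants, Boltzmann
#' factor, smoothing window, simulation settings...).  Missing keys keep
#' the supplied defaults.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param defaults named list of default values.
#' @return named list.
#' @export
read_run_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}
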