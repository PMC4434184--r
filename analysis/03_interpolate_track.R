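#!/usr/bin/env Rscript

# Stage 3: upsample the mock experimental track.
#
# The coarse 10-bp-bin occupancy profile is interpolated to per-bp
# resolution with a natural cubic spline through the bin midpoints
# (independent runs across data gaps, no extrapolation), then
# log-ratio normalized, mirroring how a binned nucleosome-sequencing
# profile is brought onto the same footing as the per-bp prediction.

suppressMessages(library(nucelastic))
indir <- "results/sim/depletion"
outdir <- "results/experimental"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ct <- read_coarse_track(file.path(indir, "coarse_track.bedGraph"))
tracks <- spline_interpolate(ct)
for (sid in names(tracks)) {
  ntr <- normalize_occupancy(tracks[[sid]])
  write_bedgraph(ntr, file.path(outdir, paste0(sid, ".bedGraph")))
  cat(sprintf("%s: %d bins -> %d bp interpolated\n", sid,
              sum(ct$seq_id == sid), sum(!is.na(ntr$values))))
}
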