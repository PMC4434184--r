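#!/usr/bin/env Rscript

# Stage 2: sequence-dependent occupancy prediction.
#
# Scores every dyad placement on the depletion-study genome with the
# elastic forced-bending model, converts energies to Boltzmann formation
# potentials (beta = 1), averages them over the 51-bp occupancy window,
# and writes the log-ratio-normalized per-bp track as bedGraph.

suppressMessages(library(nucelastic))
indir <- "results/sim/depletion"
outdir <- "results/predicted"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

seqs <- Biostrings::readDNAStringSet(file.path(indir, "genome.fa"))
tab <- step_param_table()
for (sid in names(seqs)) {
  tr <- occupancy_profile(as.character(seqs[[sid]]), tab, seq_id = sid)
  ntr <- normalize_occupancy(tr)
  write_bedgraph(ntr, file.path(outdir, paste0(sid, ".bedGraph")))
  cat(sprintf("%s: %d bp scored, normalized occupancy range [%.2f, %.2f]\n",
              sid, sum(!is.na(ntr$values)), min(ntr$values, na.rm = TRUE),
              max(ntr$values, na.rm = TRUE)))
}
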