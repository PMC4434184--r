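#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Two data sets are produced under results/sim/:
#   depletion/  a 250-kb genome carrying 50 stranded pseudogene-like
#               features (25 "transcribed", 25 "nontranscribed"), each
#               flanked by a 150-bp dA:dT nucleosome-inhibitory run
#               immediately upstream of its start anchor and downstream
#               of its end anchor, plus a mock experimental occupancy
#               track at 10-bp resolution with noise and painted dips at
#               the element centres.
#   families/   50 pseudogene families x 20 members (400 bp, parent GC
#               0.55, per-member mutation rates graded 0..0.35 with an
#               0.85 AT bias), so identity and GC decay together as in
#               ageing processed pseudogenes.
# Ground truth (element coordinates, dip parameters, member attributes)
# goes into each manifest.json for the downstream recovery stages.

suppressMessages(library(nucelastic))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
outdir <- "results/sim"

g <- simulate_genome(250000, gc = 0.41, seed = seed + 1000L)
sim <- simulate_features_with_depletion(
  g, n_per_group = c(transcribed = 25L, nontranscribed = 25L),
  feature_length_range = c(600L, 2000L), element_length = 150L,
  min_gap = 2200L, seed = seed + 1000L)
dip_centers <- data.frame(seq_id = sim$elements$seq_id,
                          center = (sim$elements$start +
                                    sim$elements$end) / 2)
ct <- simulate_coarse_track(sim$sequences, dip_centers, bin_size = 10L,
                            baseline = 1, noise_sd = 0.05,
                            dip_depth = 0.5, dip_sd = 60,
                            seed = seed + 1500L)
paths <- write_simulation(file.path(outdir, "depletion"), sim$sequences,
                          sim$features, ct,
                          manifest = list(seed = seed,
                                          elements = sim$elements,
                                          dip = list(depth = 0.5, sd = 60,
                                                     noise_sd = 0.05)))
cat("depletion study:", nrow(sim$features), "features,",
    nrow(sim$elements), "inhibitory elements ->",
    file.path(outdir, "depletion"), "\n")

cohort <- simulate_family_cohort(n_families = 50L, members_per_family = 20L,
                                 member_length = 400L, parent_gc = 0.55,
                                 max_rate = 0.35, at_bias = 0.85,
                                 seed = seed + 2000L)
write_simulation(file.path(outdir, "families"), cohort$sequences,
                 cohort$features,
                 manifest = list(seed = seed, n_families = 50L,
                                 members_per_family = 20L,
                                 max_rate = 0.35, at_bias = 0.85))
cat("family cohort:", nrow(cohort$features), "members in 50 families ->",
    file.path(outdir, "families"), "\n")
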