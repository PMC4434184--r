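---
title: "Predicting nucleosome occupancy from DNA bending energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nucleosome occupancy from DNA bending energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A nucleosome wraps about 147 bp of DNA around a histone octamer. Whether a
particular stretch of genomic DNA accommodates that wrap cheaply depends on
its sequence, because the elastic properties of a dinucleotide step — how
easily it rolls and tilts, and what roll and tilt it prefers at rest — vary
with the two bases involved. `nucelastic` scores this with a forced-bending
model of the nucleosomal superhelix.

Each base pair is treated as a rigid body whose orientation relative to its
neighbour is described by the Cambridge-Convention step parameters. Bending
is carried entirely by roll ($\rho$) and tilt ($\tau$); twist is frozen at a
uniform $\omega = 34.8^\circ$ per step, the average of the 1kx5
nucleosome crystal structure. Steps are indexed from the dyad,
$i = \pm1, \pm2, \dots$, with step $\pm1$ half a step away, so the
accumulated twist at the centre of step $i$ is

$$\Omega_i = \operatorname{sign}(i)\,\bigl(\tfrac{1}{2} + (|i|-1)\bigr)\,\omega .$$

The octamer is modelled as exerting a uniform torque $F_b$ on the wrapped
DNA. Under that torque a step deforms away from its equilibrium angles in
proportion to its compliance and to its rotational phasing:

$$\rho(i) - \rho_0(i) = \frac{F_b \cos\Omega_i}{k_\rho(i)}, \qquad
  \tau(i) - \tau_0(i) = \frac{F_b \sin\Omega_i}{k_\tau(i)},$$

with harmonic energy

$$E_b(i) = \frac{F_b^2}{2k_\rho(i)}\cos^2\Omega_i +
           \frac{F_b^2}{2k_\tau(i)}\sin^2\Omega_i .$$

Only the central 129 bp of the footprint contact the octamer (the outer
stretch at either end carries no sequence-dependent signal), and that
contacted stretch must bend by $\alpha = 579^\circ$ in total:

$$\alpha = \sum_{i=\pm1}^{\pm64} \rho(i)\cos\Omega_i + \tau(i)\sin\Omega_i .$$

Solving the constraint for the torque gives

$$F_b = \frac{\alpha - \sum_i \rho_0(i)\cos\Omega_i - \sum_i \tau_0(i)\sin\Omega_i}
             {\sum_i \cos^2\Omega_i / k_\rho(i) + \sum_i \sin^2\Omega_i / k_\tau(i)},$$

and the placement energy is $E = \sum_i E_b(i)$. Because the torque is
defined by the bend constraint, the realised bend angle recomputed from the
deformed angles returns $\alpha$ exactly for every valid placement;
`total_bend_angle()` exists to make that conservation checkable, and the
test suite verifies it to $10^{-6}$ degrees on random windows.

The ten canonical parameter rows (`inst/extdata/step_params.tsv`) are force
constants and equilibrium angles averaged over a large pool of
protein-bound DNA structures. They are expanded to all 16 steps by strand
symmetry: a step and its reverse complement are the same physical stack
read from opposite strands, so they share $k_\rho$, $k_\tau$ and $\rho_0$,
while tilt — which is antisymmetric under strand reversal — takes
$\tau_0 \mapsto -\tau_0$. All four palindromic steps have $\tau_0 = 0$,
as consistency requires. This expansion is what makes the placement energy
exactly strand symmetric, a property the tests verify numerically rather
than assume.

Energies are left in the arbitrary units implied by the constants, with
angles in degrees. Only energy differences matter downstream.

## From energy to occupancy

The Boltzmann weight of forming a nucleosome centred at position $j$ is
$S_j = e^{-\beta E_j}$ with $\beta = 1$ (the temperature scale is absorbed
into the arbitrary energy units). Occupancy at a base pair is the average
formation potential over a sliding window of $l = 51$ bp:

$$O_j = \frac{1}{l} \sum_{i=j-(l-1)/2}^{j+(l-1)/2} S_i ,$$

and a normalized occupancy is the log-ratio against a reference mean,
$O^{nor}_j = \log\!\left(O_j / \langle O \rangle\right)$.

Numerical and edge decisions, made once and recorded here:

* **Summation index sets.** The contact window has 128 steps,
  $i = \pm1 \dots \pm64$; there is no step 0, and every sum skips it.
* **Truncated windows.** Near sequence ends, and next to ambiguous bases,
  the $l$-bp window is truncated to the defined potentials it contains; a
  position is `NA` only when its window holds none. The boundary regions
  are precisely the object of study, so discarding them by default would
  be self-defeating; `full_window_only = TRUE` restores the strict rule.
* **Ambiguous bases.** A placement whose contact window contains an `N`
  is undefined and propagates as missing — there is no parameterization
  for ambiguous steps and imputing one would manufacture signal.
* **Log base.** Natural log; any base is a monotone rescaling, and the
  choice is recorded in the track metadata.
* **Reference mean.** By default the mean defined occupancy of the track
  being normalized. When several sequences are compared — the family
  cohort analysis in particular — a single cohort-wide reference must be
  passed instead, otherwise per-sequence normalization removes exactly
  the between-sequence differences under study.
* **Windowed summation.** The occupancy average is computed with
  windowed moving sums rather than differences of cumulative sums:
  formation potentials can span a hundred orders of magnitude along one
  chromosome, and cumulative-sum differencing cancels catastrophically.

## Upsampling coarse experimental tracks

Experimental nucleosome maps often arrive as binned coverage (10-bp bins
here). To put them on the same per-bp footing as the prediction, a natural
cubic spline is fitted through the bin midpoints of each contiguous run of
bins and evaluated at every integer position between the outermost knots.
The knot sits at the bin midpoint because a bin value summarizes its whole
bin; the natural boundary condition (zero second derivative) is the
conservative default and `"fmm"` is exposed as an alternative. Runs are
broken at any gap in the bins — bridging missing data with a polynomial
would invent structure — and runs of fewer than four knots fall back to
linear interpolation. The spline passes through every knot exactly and
reproduces constant and linear bin sequences everywhere, which the tests
assert; a cubic polynomial is reproduced to $10^{-6}$ away from the run
boundaries (and exactly, everywhere, under `"fmm"`).

## Metaprofiles and family statistics

`aggregate_profile()` averages any per-bp track in transcription
orientation around feature start or end anchors: for a minus-strand
feature the start anchor is its higher genomic coordinate and the
extracted window is reversed, so positive offsets always point into the
feature body from a start anchor and away from it at an end anchor.
Per-offset counts are reported, missing signal just thins them, and the
default flank is 1000 bp. Profiles are emitted as raw per-offset means,
unsmoothed.

`family_correlations()` computes, per family, the Spearman correlation of
per-feature mean occupancy with GC content, identity to the parent gene,
and divergence. Choices: significance is two-sided at $\alpha = 0.05$ with
no multiple-testing correction, because family-level counts are reported
raw ("41 of 77 families significant") and a correction would change what
is being counted; ties get average ranks; p-values use the large-sample
t approximation, switching to the exact permutation distribution for
families of at most 10 usable pairs; families with fewer than 5 usable
pairs (configurable) are reported untested rather than silently absorbed.
Features shorter than one 129-bp contact length cannot be scored by the
model at all and are excluded from predicted-occupancy means.
`group_anova()` is the classical equal-variance one-way F test on
per-feature means, with the degenerate all-identical case defined as
$F = 0$.

## What the synthetic data emulates

The generator exists so that every stage has a recovery test with known
ground truth, with no downloads:

* **Genomes** are i.i.d. bases at a target GC (default 0.41, the human
  genome-wide value).
* **Features with depletion elements**: stranded pseudogene-like
  intervals (50 by default, 600–2000 bp, at least 2.2 kb apart so
  profile windows do not overlap neighbours) with a 150-bp homopolymeric
  dA:dT run written immediately upstream of each start anchor and
  downstream of each end anchor, strand-respecting. dA:dT tracts are
  genuinely nucleosome-disfavouring under the step parameters (the AA/TT
  step is the stiffest in roll), so the predicted-occupancy pipeline
  recovers a real sequence-level signal, not a painted one. The element
  length was chosen at the scale of a nucleosome-depleted region.
* **Family cohorts** (50 families × 20 members of 400 bp by default,
  roughly the scale of ribosomal-protein pseudogene sets): one parent per
  family at GC 0.55 (coding-like), members substituted at rates graded
  from 0 to 0.35 with an 0.85 AT bias, so identity and GC decay together
  as they do in ageing processed pseudogenes. Recorded identity and GC
  are exact recomputations from the realised sequences; divergence is
  recorded as the member's mutation rate. Substitutions only — no
  indels, no phylogeny.
* **Coarse tracks** are baseline-plus-Gaussian-noise bins (10 bp) with
  smooth dips painted at the element centres, independently of the
  sequence — mirroring the fact that in vivo occupancy reflects
  remodellers, modifications and polymerase traffic on top of sequence.

What passing these recovery tests does **not** show: that the model's
absolute occupancies are calibrated against any real nucleosome map, that
real nucleosome-depleted regions are homopolymer runs, or that real
pseudogene families satisfy the generator's clean monotone
identity–GC–divergence coupling. The synthetic cohort is deliberately
idealized; it validates the machinery, not the biology.

## Problem sizes and determinism

The shipped analyses use a 250-kb genome with 50 features for the
depletion study and 1000 member sequences of 400 bp for the family
cohort — sizes at which every stage completes in seconds while leaving
per-offset and per-family sampling noise clearly below the effects being
recovered. Every generator takes an explicit seed and is fully
deterministic under it; re-running any stage with the same seed
reproduces its outputs exactly.

## Known limitations

* Only roll and tilt deform; slide/shift/rise are ignored and twist is
  constant, as the model defines.
* Occupancy is a window-averaged Boltzmann weight of independent
  placements: there is no steric competition between overlapping
  nucleosomes, so predicted occupancy is an intrinsic sequence
  preference, not an equilibrium coverage.
* The 129-bp contact length is normative here; the ~10 bp of uncontacted
  DNA per end quoted for crystal structures would suggest 127, but 129 is
  what the bend-angle constraint and the minimum-length rule are defined
  on, and the geometry is configurable.
* Divergence in the family generator is a rate proxy, not a
  substitutions-per-site estimate from an alignment; real divergence
  values arrive as input attributes.
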