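---
title: "Chromatin tracing of an imprinted domain: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin tracing of an imprinted domain: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtrace)
```

## What this package computes

`chromtrace` reconstructs the 3D folding of a contiguous genomic domain from
sequential DNA-FISH ("chromatin tracing") data and compares folding between
conditions. The motivating application is the human 15q11.2-q13 imprinting
domain: patient fibroblasts from Prader-Willi (PWS) and Angelman (AS)
syndromes carry a deletion of this region on the paternal or maternal
homolog respectively, so each line exposes exactly one traceable allele —
maternal in PWS cells, paternal in AS cells. Tracing both lines and
contrasting them therefore measures allele-specific chromatin compaction.

The pipeline has six stages, each usable on its own:

1. **Panel design** — tile the target region into consecutive 50-kb
   segments, design repeat-filtered 30-nt targeting sequences, assemble
   130-nt template and 60-nt adapter oligos, and assign each segment to a
   (hybridization round, color channel) slot.
2. **Synthetic data** — generate ground-truth polymer conformations and
   simulated imaging observations so every downstream stage is testable
   without any experimental download.
3. **Registration** — estimate and apply chromatic and per-round drift
   corrections, segment nuclei, and fit 3D foci restricted to nuclei.
4. **Trace linking** — assemble registered foci into per-nucleus traces and
   refit missing loci from a relaxed candidate pool.
5. **Distance statistics** — median spatial-distance matrices, log2
   fold-change maps between conditions, compaction summaries.
6. **Concordance** — correlation of imaged median distances with a binned
   chromatin contact-frequency matrix over the same bins.

## The probe panel

The default region is chr15:23,500,000-25,600,000 (hg38), which tiles into
exactly 42 segments of 50 kb read out over 21 two-color rounds (two
segments per round, one per dye channel). The source protocol states the
region end inconsistently — 25,650,000 in one place (2.15 Mb, which would
give 43 tiles) and "2.1 Mb / 42 consecutive 50-kb segments" in another. We
default to the segment count, ending the panel at 25,600,000; both numbers
are one config field away.

Each template oligo concatenates, 5'→3': a 20-nt forward priming sequence,
a 20-nt readout (secondary-probe binding) site, the 30-nt genome-targeting
sequence, two further 20-nt readout sites, and a 20-nt reverse priming
site — 130 nt in total. All oligos of one segment share the same readout
sites, so a single 60-nt adapter (a 20-nt primary-binding half that
reverse-complements the readout site, plus two identical copies of the
common readout binding sequence) routes the whole segment to the round's
dye-labeled readout oligo.

Repeat screening replaces alignment against a repeat database with exact
sub-k-mer counting: a candidate is kept only if every 17-mer inside it
occurs at most once in the supplied genome (both strands). This is
deterministic, needs no external tool, and is testable against a
brute-force genome scan — the trade-off is that it only sees exact
repeats, which is adequate for the synthetic genomes the package targets
and a reasonable first-pass filter on real ones. Composition defaults (GC
between 0.30 and 0.70, homopolymers at most 6 nt) follow common
oligo-FISH practice; the protocol itself is silent on them. Since an
overlap shorter than 17 nt with a repeat leaves no repeated 17-mer in the
candidate, candidates brushing a repeat edge can survive; this is a
property of any sub-k-mer screen, not a bug.

Primer and readout handles are drawn from a seeded random pool with
pairwise Hamming distance ≥ 8 and reverse-complement cross-screening. The
published handle sequences are not reproduced.

## The synthetic generator

The generator is first-class, tested code: its defaults *are* the study
conditions for every property test in the package.

**Polymer model.** Each allele is an ideal Gaussian chain: locus positions
are cumulative sums of isotropic Gaussian steps with per-axis standard
deviation `scale * step_sigma` (default 120 nm per 50-kb step). The chain
gives closed forms the tests exploit — `E[d²(i,j)] = 3·(s·σ)²·|i−j|`, a
Maxwell distance distribution per pair, and a chi-square contact
probability — and it reproduces the one qualitative regime the analysis
needs: strong anti-correlation between median distance and contact
frequency. It is *not* a mechanistic model: no excluded volume, no
loop extrusion, no territories. Passing tests therefore demonstrate that
the reconstruction and statistics are correct, not that real chromatin is
a Gaussian chain.

A condition is a compaction factor: `scale = 0.8` makes every distance 20%
smaller (log2 fold change `log2(0.8) ≈ −0.32` entrywise). A `sub_block`
override rescales only the steps internal to a locus range, planting a
sub-region whose compaction change opposes the rest of the domain — the
synthetic analog of a locally reversed fold-change sign.

**Observation model.** Per round: a rigid drift uniform in ±300 nm per
axis (round 0 is the undrifted reference), a constant chromatic offset
(60, 40, 0) nm on the 560-nm channel, localization noise of 50 nm
laterally and 100 nm axially (axial worse because of 200-nm z-stepping),
hard dropout with detection probability 0.9, lognormal brightness whose
lower tail falls below the default detection threshold, and Poisson(3)
nonspecific foci per nucleus per round uniform in a 6-µm nucleus. Twenty
fiducial beads are imaged every round in their own (488-nm) channel, and
multi-color beads appear in both readout channels for chromatic
calibration. None of these magnitudes is reported by the source protocol;
they are implementation choices picked to be realistic yet desk-solvable,
and all are `simulation_config()` fields. `noiseless_config()` zeroes
every noise term — including the brightness spread, since a dim-but-real
focus is an observation defect like any other — which is what makes the
end-to-end identity test exact.

An optional raster mode (`render_zstack()`, `fit_foci(zstack=)`)
rasterizes foci onto a (108, 108, 200)-nm voxel grid with a Gaussian PSF,
Poisson shot noise and constant background, for testing the 3D Gaussian
spot refinement; the vector mode (foci tables) is the primary path.

## Registration

Corrections are estimated and applied in the order the experiment creates
them: chromatic first (within a round, mapping the 560-nm channel into the
647-nm reference frame), then per-round drift (mapping every round into
round 0). Bead matching uses mutual nearest neighbors within a gate
(500 nm chromatic, 2 µm drift — the drift gate must exceed the largest
drift). The chromatic model defaults to a pure translation; a full affine
fit sits behind `mode = "affine"` and needs four non-coplanar matches. The
drift estimator is the mean matched displacement, with a trimmed variant
(worst 20% of matches dropped) behind `robust = TRUE`. With both the round
and the reference localizations jittered by σ, the per-axis standard error
of a drift estimate is √2·σ/√n — the factor the tests bound against.

Nucleus segmentation is a pass-through in vector mode (the simulator
declares centers and radii) and Otsu threshold + connected components +
minimum-area filter in raster mode, with labels assigned in deterministic
raster-scan order. Foci fitting restricts detections to nuclei with a
slack factor (default 1.2× the nominal radius) because drift and noise can
push a genuine peripheral focus slightly outside the nominal sphere.

## Trace linking

The codebook maps each (round, channel) to exactly one locus, so linking
is: find the trace's center, let the correct-round-and-channel foci within
`r_max` (default 1500 nm) compete per locus, and choose the assignment
minimizing total cost — summed distance to the centroid of the assigned
foci minus `intensity_weight · Σ log(intensity)` (default weight 0, purely
spatial). The centroid makes the objective self-consistent, so the
minimization is done exactly by enumeration when the number of candidate
combinations is small (≤ 4096; the common case, since most loci have one
candidate) and by iterative centroid refinement otherwise. Ties break to
higher intensity, then lower round index — full determinism, which the
shuffled-input test asserts. One trace per nucleus is the default
(hemizygous deletion lines); `expected_traces_per_nucleus = 2` splits
foci by average-linkage clustering first, for stress-testing.

Chain ends sit farthest from the trace centroid, so an end locus
occasionally falls outside `r_max` and is left missing by the linker. The
refit stage recovers it: the expected position of each missing locus is
interpolated linearly between the nearest present loci (extrapolated at
the ends), and the nearest correct-slot candidate within `refit_radius`
(500 nm) at a relaxed intensity threshold (× 0.5) is adopted and flagged
`refit`. Assigned loci are never overwritten and foci never reused, so
refitting can only increase completeness. Linking plus refit is what makes
the noiseless reconstruction exactly equal the planted coordinates.

## Distance statistics and concordance

Median distance matrices are pairwise-complete: a trace missing either
locus is skipped for that entry, the number of contributing traces is
recorded, and entries with fewer than `min_pairs` (default 10)
observations are reported missing rather than noisy. Medians of even
counts use the midpoint convention. Fold-change maps are entrywise
`log2(D_num/D_den)`, exactly antisymmetric under swapping conditions, with
zero denominators turned into missing entries with a warning. Bootstrap
CIs (1000 percentile resamples, seeded) accompany compaction summaries and
region sign fractions; the source analysis reports no uncertainty
procedure, so this is the package's own choice.

Contact matrices are consumed as plain text (dense TSV with
`chrom:start-end` labels, or sparse upper-triangle COO); binary Hi-C
formats are out of scope. Bins are matched to panel segments by
chromosome and start coordinate at equal bin width; the correlation over
matched pairs defaults to Pearson on raw values with Spearman and log
transforms as options, since the source analysis does not state which
produced its printed coefficients. Zero contacts under a log transform are
excluded and counted, never pseudocounted silently. An optional
`min_separation` drops near-diagonal pairs.

Note one systematic effect the tests quantify: localization noise adds to
distances in quadrature, so short-separation entries are inflated and a
reconstructed fold-change median is slightly attenuated toward zero
relative to the ground-truth `log2(s)` (about 0.04 at the default noise
levels and s = 0.8). The parameter-recovery tests pass at ±0.05 at both
the ground-truth and the full-pipeline level; sharper recovery would
require noise deconvolution, which is out of scope.

## Reproducibility and problem sizes

Every stage draws from a named substream derived from one top-level seed,
so reruns are byte-identical and editing one stage never perturbs another.
The test suite uses panel-sized problems where the property needs them
(42 loci; 500 traces per condition for parameter recovery; 1000 traces for
concordance direction; 200 seeded instances for the linking oracle) and
toy sizes everywhere else; these sizes are the package's choice of where
Monte-Carlo error becomes negligible relative to the tested tolerances.

## Known limitations

- The Gaussian chain cannot produce TADs, loops, or compartment structure;
  concordance checks direction and strength of the distance/contact
  relationship, not map morphology.
- The sub-k-mer repeat screen sees exact repeats only.
- The chromatic model is rigid (translation or affine); field-dependent
  distortion is not modeled.
- One condition's contact matrix is derived from the simulated ensemble;
  consuming an experimental matrix requires only the dense-TSV dump.
- The panel's codebook is one-segment-per-slot; combinatorial
  (error-correcting) barcoding schemes are out of scope.
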