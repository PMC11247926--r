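# chromtrace

Chromatin tracing by sequential DNA-FISH: probe-panel design, trace
reconstruction, and allele-specific distance statistics in R.

## The problem

Chromatin tracing localizes consecutive genomic segments in 3D by
sequential hybridization imaging and links them into per-allele polymer
traces — an imaging analog of Hi-C that yields *distances in nanometers*
per single allele instead of population-averaged contact counts. The
motivating application is the human 15q11.2-q13 imprinting domain:
Prader-Willi (PWS) and Angelman (AS) syndrome fibroblasts carry a deletion
of the region on the paternal or maternal homolog, so each line exposes
one traceable allele, and contrasting the two lines measures
allele-specific compaction of the imprinted domain.

`chromtrace` is for computational biologists who want a tested, seeded,
end-to-end implementation of that computation: it covers oligo panel
design, a synthetic polymer/imaging generator (so everything is testable
without experimental downloads), registration, trace linking, distance
statistics, and concordance with binned contact maps.

## The computation

- **Panel**: the target region (default chr15:23,500,000–25,600,000,
  hg38) is tiled into 42 consecutive 50-kb segments, read out over 21
  two-color rounds. Per segment, 500 template oligos are designed; each is
  the 130-nt concatenation (5'→3') of a 20-nt forward primer, a 20-nt
  readout site, a 30-nt genome-targeting sequence screened so that every
  17-mer in it is unique genome-wide, two more 20-nt readout sites, and a
  20-nt reverse-primer site. A 60-nt adapter per segment routes its probes
  to the round's dye-labeled common readout.
- **Simulator**: each allele is a Gaussian chain, locus positions the
  cumulative sum of isotropic steps with SD `s·σ` (σ = 120 nm per 50-kb
  step, `s` the condition's compaction factor), so
  `E[d²(i,j)] = 3(sσ)²|i−j|`. The observation model adds per-round drift,
  a chromatic offset on one channel, anisotropic localization noise,
  dropout, brightness noise and nonspecific foci.
- **Reconstruction**: chromatic and drift corrections estimated from
  beads; foci fitted inside nucleus masks; per nucleus, foci compete per
  locus and the assignment minimizing
  `Σᵢ ‖xᵢ − centroid‖ − w·Σᵢ log Iᵢ` is chosen; missing loci are refit
  near their interpolated expected positions at a relaxed threshold.
- **Statistics**: pairwise-complete median distance matrices `D`,
  fold-change maps `log2(D_A/D_B)`, radius of gyration, per-locus
  detection efficiency, and the correlation of `D` with contact frequency
  over matched 50-kb bins (strongly negative for genuine structure).

## Worked example

A two-condition run — AS at scale 1.0, PWS planted 20% more compact —
through the full simulate → register → link → statistics chain:

```r
library(chromtrace)

panel <- build_codebook(partition_region(default_tracing_region()))
panel
#> <segment_panel> 42 segments of 50,000 bp on chr15
#>   codebook: 21 rounds x 2 channels (647, 560)

cfg <- validate_config(list(
  seed = 11,
  conditions = list(
    AS  = list(scale = 1.0, n_traces = 200),
    PWS = list(scale = 0.8, n_traces = 200)
  )
))
res <- run_pipeline(cfg)
res
#> <run_result> 42 segments, 21 rounds; conditions: AS, PWS
#>   log2FC PWS_vs_AS: median -0.309 (100% entries negative)
#>   distance-vs-contact spearman r = -0.8723 (n = 861 pairs)

res$distance_matrices$PWS
#> <distance_matrix> PWS: 42 loci, 200 traces, 0 missing entries
```

Reading the numbers: the planted compaction factor 0.8 corresponds to
`log2(0.8) = −0.322`; the reconstructed median fold change of −0.309
recovers it (localization noise slightly attenuates short-range entries),
with every locus pair more compact in PWS — the planted allele-specific
compaction. The Spearman coefficient of −0.87 over the 861 locus pairs is
the expected strong anti-correlation between imaged median distance and
contact frequency. `run_pipeline(cfg, out_dir = "run1")` additionally
writes the panel BED, codebook, per-condition trace and matrix TSVs, and
a JSON report. A thin command-line wrapper over the same functions ships
in `inst/cli/chromtrace.R`.

Probe design on a real or synthetic FASTA:

```r
genome <- random_dna(50000, seed = 1)          # one-record toy genome
idx    <- build_kmer_index(genome, sub_k = 17)
cand   <- extract_candidate_targets(genome, k = 30)
sel    <- select_probes(filter_repetitive(cand, idx))   # 500 probes
```

## Documentation

The methods vignette (`vignettes/chromatin-tracing.Rmd`) describes the
polymer and observation models, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
package's numerical conventions (tie-breaks, median convention,
missing-entry policy).
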