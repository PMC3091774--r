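---
title: "Genotyping and QTL mapping in chromosome segment substitution lines"
author: "csslmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and QTL mapping in chromosome segment substitution lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csslmap)
```

## The experimental design

A chromosome segment substitution line (CSSL) carries one or a few
homozygous donor chromosome segments in an otherwise uniform
recurrent-parent background. A library of such lines tiles the donor
genome across the population, so any trait difference between a line and
the recurrent parent can be attributed to the segments that line carries.
`csslmap` implements the full analysis chain for such libraries in rice:

1. **Simulation** of CSSL populations (either by explicit
   backcross/selfing meiosis or by planting segments from a target
   distribution), of parent-discriminating SNP catalogs, of sparse PCR
   marker genotypes, of low-coverage per-site SNP origin observations,
   and of line-mean phenotypes from a linear bin-effect model.
2. **Marker-based genotyping**: the graphical-genotype DD/DR/RR rule that
   turns sparse marker calls into substituted-segment estimates.
3. **Sequencing-based genotyping**: sliding-window origin calling over
   low-coverage SNP observations, with dynamic window size, hierarchical
   refinement and midpoint breakpoint placement.
4. **Population summaries**: segment counts, per-chromosome and genome
   fold coverage, union coverage rates, segment length statistics.
5. **Bin-map construction**: the genome partition induced by all lines'
   segment breakpoints, and the corresponding line-by-bin matrix of
   ±1 genotype codes.
6. **QTL mapping**: stepwise multiple linear regression of phenotype on
   the ±1 codes with F-based entry/stay thresholds and sequential
   partial R² decomposition, reported as a classed model object.

## Coordinate conventions

All intervals are 1-based with an exclusive end, so `size = end - start`.
A segment written `1-1171547` therefore spans 1,171,546 bp. BED export
subtracts one from both bounds (`bed_start = start - 1`,
`bed_end = end - 1`), giving standard 0-based half-open records.
Midpoints are integer floors of `(a + b) / 2`, which keeps every
coordinate deterministic on integer base-pair positions.

## The synthetic-data generator

No CSSL data set accompanies the method, so the generator is a
first-class, tested module that emulates the statistical structure the
analysis assumes:

* **Genome** — `rice_genome()`: 12 chromosomes totalling 372.2 Mb,
  back-derived from the published per-chromosome coverage relations.
* **Population shape** — `plant_segments()` draws per-line segment
  counts from weights (default 54, 41, 18, 8, 5, 2 for 1–6 segments,
  mean ≈ 2.02 segments/line over 128 lines) and segment lengths
  log-uniform over 0.2–22 Mb. The log-uniform choice reproduces the
  published skew (most segments short, mean ≈ 4.9 Mb); a uniform draw
  would more than double the mean. Placement is uniform with
  non-overlap enforced by bounded retries.
* **Breeding route** — `simulate_breeding()` follows one plant per
  candidate through backcrossing and selfing with Poisson crossover
  counts (mean = genetic length in Morgans at a constant 4 cM/Mb,
  rice-typical), uniform crossover positions and no interference
  (Haldane model). Marker-assisted selection is idealized: candidates
  are kept when their true homozygous segment count is between 1 and
  `mas_max_segments`. Final lines are modeled as fully homozygous; the
  expected homozygous donor fraction of an unselected line is
  $0.5^{\,n_{bc}+1}\,(1 - 0.5^{\,n_{self}})$, which approaches the
  classical $0.5^{\,n_{bc}+1}$ as selfing deepens.
* **Parent SNP catalog** — `simulate_parents()` plants ~3.1 SNPs/kb
  (≈1.16 million sites genome-wide), the density of a typical
  indica × japonica contrast.
* **Observations** — `simulate_snp_observations()` observes each catalog
  site independently with probability `coverage` (default 0.13,
  matching a 0.13× re-sequencing experiment) and flips the observed
  origin with probability `error_rate` (default 1%, sequencing plus
  alignment noise). Base qualities and depths are attached so the
  catalog filters can be exercised.
* **Phenotypes** — `simulate_phenotypes()` evaluates
  $y_i = b_0 + \sum_k b_k x_{ik} + e_i$ with $x_{ik} = \pm 1$ donor
  codes and normal residuals; `effect_for_r2()` sizes an effect so one
  locus explains a target variance fraction (the default study plants a
  ~70% locus, emulating a semi-dwarfing allele segregating for culm
  length around 124 cm with 6 cm residual sd).

What the generator does **not** emulate: read-level sequencing (FASTQ,
alignment, demultiplexing), segregation distortion, residual
heterozygosity in finished lines, genotype-by-environment variation, and
non-additive genetic architecture. Passing tests on synthetic data
therefore demonstrate the correctness and statistical behaviour of the
pipeline under its stated model, not robustness to every artifact of
real re-sequencing data.

All randomness flows through one explicit `seed` argument per call; the
caller's RNG state is saved and restored, so identical seeds give
byte-identical outputs.

## Marker-based genotyping

The graphical-genotype rule weights a marker interval by its flanking
calls: donor/donor (DD) intervals count fully, donor/recipient (DR)
intervals count half, recipient/recipient (RR) intervals not at all.
`call_marker_segments()` realizes this by placing each segment boundary
at the midpoint of its DR interval, so the segment length equals
DD + DR/2 + DR/2 exactly (`estimate_segment_length()`). Two conventions
complete the rule where the published description is silent:

* A donor run touching the first (last) polymorphic marker of a
  chromosome extends to the chromosome start (end) — there is no
  recipient flank to halve, and published QTL intervals starting at
  position 1 show chromosome-terminal segments were allowed.
* Missing calls are transparent: runs are computed over non-missing
  markers, standard graphical-genotype practice.
* Heterozygous calls are an error in finished-line mode; with
  `allow_het = TRUE` (intermediate generations) they count as
  donor-informative.

## Sequencing-based genotyping

Individual low-coverage origin calls are too noisy to genotype directly,
so `seq_genotype()` evaluates a sliding window of consecutive SNP calls:
a window is called donor when at least `ceiling(0.8 × window)` of its
votes are donor, recipient symmetrically, ambiguous otherwise. Design
choices, in order of consequence:

* **Dynamic window size** (`auto_window_size()`): at least 15 SNPs,
  scaled so one window spans ≈ 200 kb at the line's observed SNP
  density, and forced odd so windows have centers. At 0.13× coverage of
  a 3.1 SNPs/kb catalog this gives windows of ~80 SNPs. The 15-SNP
  floor follows the sliding-window genotyping lineage for low-coverage
  populations; 0.8 keeps the binomial tail probability of a false
  window call negligible (at 10% call noise,
  $P(\ge 12/15) \approx 1.4\times 10^{-9}$ per window).
* **Ambiguous windows**: an interior run of ambiguous windows between
  two *differing* blocks is split at its midpoint. Absorbing such runs
  one-sidedly (e.g. always into the preceding block) shifts every
  breakpoint in the same direction by ≈ (threshold − ½) × window span —
  a systematic ~60–85 kb bias at the default settings, which midpoint
  splitting removes. Runs at a chromosome edge, or between agreeing
  blocks, are absorbed whole; a run longer than one window raises a
  low-confidence message.
* **Hierarchical refinement**: a density-scaled window cannot resolve a
  gap between two same-line segments narrower than one window span —
  precisely the double-crossover products high-density genotyping is
  meant to catch. Each merged block is therefore re-scanned at the
  15-SNP minimum window and split when the small-window evidence
  supports it. At 1% call error the false-split probability per window
  is ~2 × 10⁻¹⁹, so refinement does not degrade the noise robustness
  of the coarse pass.
* **Breakpoints** are placed at the integer midpoint between the last
  supporting SNP of one block and the first of the next, mirroring the
  marker-map convention; blocks touching a chromosome's first or last
  informative SNP extend to the chromosome end. Whether the original
  implementation used midpoints or last-concordant SNPs is not
  recorded; midpoints are symmetric and unbiased.
* Repeated observations of one site in one line are resolved by
  majority, dropping ties — the per-line analogue of excluding
  conflicting-genotype sites during parent SNP discovery.

Parent SNP discovery (`filter_parent_snps()`) applies the published
filters verbatim: bases below Phred 25 removed, sites with conflicting
surviving reads excluded, sites at depth ≥ 100 excluded (copy-number
guard), and a site enters the catalog only when the two parents'
consensus bases differ.

## Bin maps

Pooling all lines' segment start/end breakpoints per chromosome and
cutting at each unique breakpoint yields intervals within which no line
changes genotype; those inside the union of donor segments are the
**bins** (`build_bins()`). Regions never substituted in any line carry
no genotype contrast and are not bins — the published bin count times
mean bin size reproduces the union coverage, not the genome length,
which fixes this choice. `bin_genotypes()` fills the ±1 line × bin
matrix; `validate_bins()` drops constant columns and collapses exactly
identical columns to their leftmost representative, recording each
group's merged physical span: a QTL mapped to a representative is only
localized up to that span, and `qtl_report()` widens the interval
accordingly.

## Stepwise QTL mapping

`cssl_qtl()` fits $y_i = b_0 + \sum_k b_k x_{ik} + e_i$ by classic
F-based stepwise selection: the candidate with the smallest entry
p-value (partial F given the current model, 1 numerator df) enters while
p ≤ `slentry`; after each entry, included bins with partial-F p >
`slstay` are removed, worst first; selection stops when nothing can
enter, or when the next entry is the variable just removed (cycle
guard). Both thresholds default to 0.01. Ties on p go to the leftmost
bin, making runs deterministic. p-values come from the F(1, n − k − 1)
distribution at each evaluation; no multiple-testing correction is
applied beyond the fixed thresholds.

The explained variance is decomposed **sequentially**: a bin's partial
R² is the increase in model sum of squares at its entry divided by the
total sum of squares, so the running model R² is the cumulative sum of
partials — the published QTL tables accumulate exactly this way. When
removals occurred, partials are recomputed by refitting the entry order
of the final model (logged). The reported F per bin is the final-model
partial F (the square of its t statistic); an entry-step F is also
visible in the trace.

Numerical notes: fits use Householder QR; exact fits (zero residual
variance) give infinite partial F for nonzero coefficients and zero for
null ones; entry statistics guard against cancellation when a candidate
completes an exact fit; candidates collinear with the current model are
skipped. Selection halts with a warning when residual degrees of freedom
fall below 2, and a constant phenotype yields an empty model with a
warning.

## Problem sizes used by the test suite

The tests run the generator at the study's own scale where the property
being checked demands it, and smaller where it does not: breakpoint
recovery uses 200 lines on a 3 × 30 Mb genome at the full 3.1 SNPs/kb
density, 0.13× coverage and 1% error; stepwise power and null
calibration use 128 lines on the full 12-chromosome genome (~440
validated bins) with 200 and 500 phenotype replicates; oracle
comparisons use ≤ 12-bin instances where exhaustive search is exact.
These sizes are the package's choice of a representative yet quickly
reproducible experiment.

## Known limitations

* Physical coordinates only; no genetic-distance (cM) bin maps.
* Final lines are assumed homozygous; heterozygous window calls are
  never emitted (a window between thresholds is "ambiguous").
* The stepwise procedure inherits the classical caveats of F-based
  selection: with many correlated bins the entry order — and hence the
  sequential decomposition — is data-dependent; orthogonal designs are
  order-invariant, correlated ones are not.
* Segments shorter than the minimum window's physical span
  (~15 × inter-SNP spacing) are below the resolution of the
  sequencing route, as are gaps of that scale after refinement.

## A worked example

```{r example, eval = FALSE}
g <- rice_genome()
maps <- plant_segments(g, n_lines = 128, seed = 1)           # truth
catalog <- simulate_parents(g, seed = 2)
obs <- simulate_snp_observations(maps, catalog, seed = 3)
grmap <- seq_genotype(obs, catalog, g)                       # GR map
coverage_summary(grmap, g)
bins <- build_bins(grmap, g)
m <- bin_genotypes(grmap, bins)
b <- effect_for_r2(maps, "chr1", 40.2e6, 0.70, 6)
ph <- simulate_phenotypes(maps, qtl_spec(
  124, data.frame(chrom = "chr1", pos = 40.2e6, effect = b), 6), seed = 4)
fit <- cssl_qtl(m, ph)
qtl_report(fit)
```

The same pipeline is scriptable from a YAML configuration via
`run_pipeline()`, which validates stage inputs before any computation
and writes every artifact (BED segment maps, TSV tables, the QTL table
and stepwise trace) with per-stage record counts logged to standard
error.
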