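---
title: "Sliding-window DMR calling for double-enzyme RRBS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window DMR calling for double-enzyme RRBS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdmr)
```

## What the package computes

Reduced representation bisulfite sequencing (RRBS) enriches the CpG-dense
fraction of a genome by restriction digest before bisulfite conversion, so
that a modest sequencing budget yields deep per-cytosine methylation calls
over regulatory regions. `rrbsdmr` implements the downstream analysis of
such data for a multi-group treatment design: starting from per-cytosine
calls (CGmap files), it identifies 100 bp regions whose CpG methylation
differs between two groups of replicates, intersects the regions called in
different comparisons to find *reversals* (regions pushed one way by an
inducing treatment and the other way by a second treatment), and assigns
each region a single genomic category and nearest gene. An in-silico digest
module models which genome fraction a double-enzyme RRBS library can see at
all, and a methylome simulator generates full synthetic data sets with
known truth so that every stage of the pipeline is testable end to end.

## The window test

Methylation levels are profiled by sliding a fixed 100 bp window in 50 bp
increments along each chromosome. Within a window, the observation unit is
one methylation ratio per (CpG site, replicate) pair: a site covered by
`total` reads of which `meth` are methylated contributes the ratio
`meth/total` for each replicate in which it is covered. The two groups'
pooled observation vectors are compared with a two-sided Mann-Whitney U
test using mid-ranks for ties, and a window is called significant when

* `p < alpha` (default 0.01, raw p-values), and
* `|mean(test) − mean(ref)| ≥ min_mean_diff` (default 0.2), and
* both groups have at least `min_window_reads` (default 10) summed reads
  over the window's CpGs and at least `min_obs_per_group` (default 3)
  observations.

Overlapping or abutting significant windows with the same direction are
merged into one DMR (`union` policy; `cpg_span` alternatively trims the
merged interval to its first and last covered CpG, which matches how short
DMRs are often printed).

Several points were genuinely open and decided as follows:

* **Observation unit.** Pooling replicates at the (site, replicate) level
  keeps within-group variability in the test and gives the U statistic
  enough observations at n = 3 replicates; per-site group means would
  leave 3-vs-3 samples whose exact test cannot reach p < 0.01 for
  single-CpG windows at all.
* **Read filter per group.** "Covered by fewer than 10 reads" is applied
  per group: each group's summed read total over the window's CpGs must
  reach `min_window_reads`. The per-site 10-read exclusion
  (`filter_coverage()`) is an independent, earlier filter; both are
  configurable separately because they act at different scales.
* **Sidedness and ties.** The test is two-sided (the reporting of hyper-
  and hypomethylated regions is symmetric) with mid-ranks; completely tied
  windows get p = 1.
* **Window boundary.** Enumerated windows are `[k·step, k·step+window)`;
  a final clipped window is kept only when *longer* than half a window, so
  a trailing 50 bp remnant of the 100/50 design is dropped.
* **Multiple testing.** Raw p-values are the default; optional
  Benjamini-Hochberg adjustment (`fdr = "bh"`) is provided as a clearly
  labelled extension.

### Exact and approximate p-values

For pooled sample sizes up to `exact_test_max_n` (default 20) the p-value
is exact: the permutation distribution of U over all `choose(n, n_x)`
assignments of the observed pooled values is evaluated by a dynamic
program over doubled mid-ranks. Doubling makes every mid-rank an integer,
so the computation is integer-exact and ties need no special casing, and
the two-sided p is `P(|U − n_x n_y/2| ≥ |u_obs − n_x n_y/2|)` (the
enumeration distribution is symmetric about `n_x n_y/2`). Larger samples
use the normal approximation with tie-corrected variance and a 0.5
continuity correction, clamped to (0, 1]. The test suite verifies the
exact path against a full bitmask enumeration that computes U by pairwise
comparison counts — an algorithmically independent route — and against
`wilcox.test()` on tie-free cases, and verifies that the approximation is
within 0.01 of the exact p at 15-vs-15.

### Conservativeness under the null

A property worth understanding before interpreting window counts: under a
true null, every CpG contributes the *same number* of observations to both
groups, all drawn around that site's mean. Site-to-site heterogeneity —
the defining feature of methylomes — is therefore balanced by design
between the groups, and the true variance of U is far below the
permutation variance the test assumes. The observed fraction of null
windows at p < 0.01 in the packaged null simulations is about 3–5 × 10⁻⁴
rather than the nominal 10⁻². (On exchangeable iid observations the
implementation is calibrated: about 0.011 at 30-vs-30; discreteness and
the continuity correction deflate small exact samples.) The window test is
thus conservative, and together with the 0.2 effect-size filter a null
genome yields zero called DMRs in the packaged simulations. The practical
consequence is that raw-p window counts should not be read as if the test
had nominal size.

## The simulator

`simulate_genome()` and `simulate_methylomes()` generate the study
conditions the analysis assumes: four treatment groups (control; inducer;
inducer plus each of two food-component extracts) with three replicates
each, configurable via `sim_config()`. Key features:

* **Genome.** Random chromosomes with CpG-depleted background (roughly
  one CG dinucleotide per 100 bp, as in a methylated vertebrate genome)
  and CpG islands (600 bp, roughly ten CG per 100 bp) covering
  `island_fraction` of the sequence; toy gene models (UTRs, three exons,
  introns, ~15% non-coding genes) and repeat intervals for the annotation
  stage. CpG coordinates are taken from the emitted sequence itself, so
  the digest, DMR and annotation stages share coordinates.
* **Methylation.** True site means are Beta-distributed — default
  Beta(1, 4) inside islands (lowly methylated) and Beta(6, 1.5) outside
  (highly methylated), giving the canonical bimodal landscape. Replicate
  means are drawn from a Beta re-parameterised around the group mean with
  concentration `replicate_noise_kappa` (default 50), which keeps ratios
  in [0, 1] — an additive Gaussian would not.
* **Coverage.** Truncated-at-1 negative binomial with mean
  `coverage_mean` (default 60, matching RRBS depths of several tens of
  reads) and variance `mu + dispersion·mu²` (default dispersion 0.1).
  The published depth range motivates overdispersion but no specific
  model; the replicate-noise and dispersion knobs are free parameters of
  the simulator, not estimates from any data set.
* **Planted truth.** `plant_dmrs_in_islands()` places fixed-width shifted
  regions (per-group signed deltas, clamped to [0, 1]) inside islands with
  a minimum CpG content, and the truth sidecar records both the regions
  and every site's true group means. Calls are emitted for the plus-strand
  C of each CpG only, so strand pooling is exercised by the CGmap importer
  rather than the simulator.

What the simulator does *not* emulate: read-level artefacts (bisulfite
conversion failure, C-to-T SNP confounding, alignment bias), chromosome-
scale covariates, or correlated methylation beyond the island/background
dichotomy. Green tests therefore demonstrate the pipeline's statistical
behaviour under its own model assumptions, not robustness to artefacts of
real libraries.

## The digest model

`digest_genome()` merges the cut maps of MspI (C^CGG) and ApeKI (G^CWGC;
W = A/T), forms inter-cut fragments, and keeps lengths in 30–500 bp;
`size_select()` models gel excision of a 160–420 bp library slice. Two
modelling decisions:

* The excised slice is interpreted as *adapter-ligated* molecule length;
  `adapter_total_bp` (default 120) converts it to an insert window of
  40–300 bp, and is configurable because protocols differ on whether the
  slice includes adapters.
* Cut geometry uses the standard top-strand offsets (both enzymes cut
  after position 1 of their motif). With single-coordinate cuts, an exact
  mirror of fragment *coordinates* under reverse complement is impossible
  for a mixed digest of a 4-mer and a 5-mer cutter (coordinates shift by
  `motif_length − 2·offset`, which differs between the enzymes). The
  strand-symmetry statement that does hold exactly — and is tested — is:
  a single palindromic-motif digest has a mirror-invariant fragment-length
  multiset, and digesting the reverse complement with the mirrored offsets
  (each site's bottom-strand cut) maps exactly onto the forward fragment
  set. Chromosome-end fragments are excluded by default since RRBS
  fragments need enzyme ends on both sides.

The in-silico 30–500 bp range is applied after merging the two enzymes'
cut maps (merge first, filter once).

## Reversal analysis and annotation

`intersect_reversed()` pairs regions from two comparisons that overlap by
at least `min_overlap_bp` (default 1 bp — the windows share a 50 bp grid,
so identity and overlap rarely differ) and have opposite directions.
`venn_counts()` tallies the four induction×treatment categories; the
headline total counts a region once per treatment that reverses it
(so a region reversed by both extracts is counted twice), and a
unique-region count is reported alongside — both tallies are emitted and
never silently reconciled. Heatmap cells are coverage-weighted mean ratios
(summed methylated over summed total reads) of a region's CpGs per sample;
rows and columns are ordered by average-linkage hierarchical clustering on
Euclidean distance, with missing cells imputed by row means for clustering
only and flagged. Leaf orders are canonicalised by weight-reordering the
dendrogram so they do not depend on input order.

Annotation assigns each DMR the highest-priority overlapping category,
default TSS > TTS > 5'UTR > 3'UTR > CpG island > Exon > Non-coding >
Repeats > Intron > Intergenic, with `Intergenic` as the no-overlap
fallback and `NA` reserved for chromosomes absent from every track. The
published analyses this mirrors do not state their resolver's order, so
the default keeps regulatory categories dominant and is fully
configurable; reproducing any specific genome-wide percentage table is
explicitly not claimed (that would require the original genome annotation
tracks). TSS/TTS windows default to 1000 bp upstream / 100 bp downstream
(and mirrored), common annotation practice.

## Worked-example fixtures

Three small tables of published DMR summaries ship with the package
(significant-DMR counts per comparison; the four reversal-category counts;
77 annotated reversed DMRs) as fixed ground truth for the counting paths.
They are integrity-checked (md5 and record count) on load, and their
marginal tallies (31 induction-hypermethylated vs 46 hypomethylated
records; 72 regions reversed by exactly one extract vs 5 by both; 61
EAT-reversed and 81 total category memberships) are recomputed by
`fixture_queries()` and `summarise_reversal_counts()` rather than stored.
The per-extract total (81) and the unique annotated-row count (77) follow
different counting rules and genuinely disagree by one even after removing
the 5 double-counted regions; both are reported as published.

## Problem sizes and numerical choices

The packaged simulations use sizes chosen to exercise every code path at
comfortable desk scale: a 1 Mb single-chromosome null genome
(~15,000 testable windows) for calibration, a 750 kb genome with 200
planted ±0.4 regions (≥10 CpGs each, coverage 30, 3-vs-3) for recovery —
which achieves sensitivity 1.0 and direction accuracy 1.0 — and 20–50 kb
genomes for unit tests. Degenerate inputs are defined, not errors: an
empty genome digests to an empty fragment set, a window without CpGs is a
skip with a machine-readable reason, `p` is clamped to (0, 1], a
completely tied window has p = 1, and a zero-coverage site contributes no
observation. Group means are clamped to [10⁻⁴, 1−10⁻⁴] before Beta
re-parameterisation to keep the replicate-noise draw well defined at the
boundaries.

## Limitations

* The DMR caller is the classical fixed-window rank-test design: no
  smoothing, no beta-binomial dispersion modelling, no covariates. Its
  null behaviour is conservative (see above), and single-CpG windows can
  never reach p < 0.01 with three replicates.
* The simulator's noise parameters are plausible rather than estimated;
  calibration claims are internal to its model.
* Annotation reproduces a priority-resolver design, not any specific
  external annotation database; category percentages depend entirely on
  the supplied tracks.
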