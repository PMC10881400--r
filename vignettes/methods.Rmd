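---
title: "Methods: staging neuronal maturation from synthetic multi-omic time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging neuronal maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neuromat` packages the quantitative procedures used to stage the
maturation of hPSC-derived cortical neurons: monotonic expression-trend
classification, a PCA-trajectory maturation score, calcium spike and
synchrony quantification, chromatin state-transition calling over a peak
atlas, and hypergeometric motif enrichment. This vignette documents the
models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was open.

## Expression trends

### Differential stand-in

Differential tables feed every trend decision. The built-in test is
deliberately simple: log fold change is the difference of group means of
`log2(RPKM + 1)`, the p-value a two-sample Welch t-test on the same
values, FDR Benjamini–Hochberg across genes. It is *not* a
negative-binomial model — no dispersion shrinkage, no independent
filtering — and `classify_monotonic()` accepts externally produced tables
(columns `gene`, `logFC`, `pvalue`, `fdr`) precisely so a full
differential pipeline can be dropped in for real data. Degenerate inputs:
if both groups have zero variance, equal means give p = 1 and unequal
means p = 0 (a certain difference under this naive model).

### Monotonic rules

The four stage contrasts are indexed 1 = d50 vs d25, 2 = d75 vs d50,
3 = d100 vs d50, 4 = d100 vs d25. "Strict" monotone-up requires FDR ≤
0.05 (inclusive) in contrasts 1, 3, 4, positive logFC in contrasts 1 and
2, and `logFC4 > logFC1`; "relaxed" requires only the endpoint contrast
to be significant, with `logFC1 > 0` and (`logFC4 ≥ logFC1` or
`logFC2 > 0`). Down rules mirror every sign, including the
endpoint-versus-first-transition comparison, which we mirror as
`logFC4 ≤ logFC1` (the inclusive mirror, matching the relaxed up rule).
All inequalities are applied exactly as written: ties at logFC = 0 fail,
FDR = 0.05 passes. Strict implies relaxed, and up/down labels are
mutually exclusive (they need opposite signs of `logFC1`) — both facts
are asserted property-style in the test suite against a literal
clause-by-clause evaluator. Genes missing from any contrast are labelled
negative rather than raising an error, tolerating per-contrast filtering
in external pipelines.

Marker selection keeps labelled genes with max |logFC| > 1 across the
four contrasts, peak timepoint-mean expression > 5 RPKM, and s.e.m. < 1
at the final timepoint (all strict inequalities).

## Trajectory scoring

Counts are variance-stabilized as `log2(x/sf + 1)` with median-of-ratios
size factors (geometric-mean reference over genes with all-positive
counts). This is a documented stand-in for a full variance-stabilizing
transform; it is monotone and adequate here because scores are only ever
compared *within* one embedding.

PCA centers each gene and decomposes by SVD; the top 3 components are
kept. Gene selection is top-N by variance (default N = 1000) or an
explicit DE-derived list. Variance ranking is the default because it
needs no extra input; workflows that rank genes by a differential
statistic pass their list through the `selection` argument. Each component's sign is
fixed by making its largest-magnitude loading positive, so embeddings are
deterministic; scores are sign-consistent regardless because both vectors
of the dot product live in the same embedding. The score uses the raw
3-D coordinates with equal weight rather than variance-weighting the
components: the score is defined on the coordinate system itself, and
re-weighting would change only the scale, not the ordering, of scores
along the control direction.

The score satisfies, for every input: score(origin) = 0,
score(control) = ‖control‖², linearity under scaling, and invariance
under translation of all centroids. These identities are asserted exactly
in the tests.

`kmeans_redundancy()` scans k upward (best of `nstart = 25` starts,
seeded) and stops when a solution becomes redundant. "Redundant" is made explicit and
configurable here: a cluster smaller than 1% of rows, or two centroids
with Pearson r > 0.95. The last non-redundant k is returned; fully degenerate input
(all rows identical) returns a single cluster with a warning.

## Calcium quantification

ΔF/F0 uses a running 10th-percentile baseline over a 30 s window
(configurable; a global percentile is available for stationary
recordings). The percentile baseline sits slightly below the mean of a
noisy trace — that is intrinsic to percentile baselines — so detection
never thresholds raw ΔF/F0 directly.

Spike detection operates on the detrended trace (clipped-window running
median, 10 s window, long relative to the transient decay; a shrinking
centered window would let a transient near the recording edge dominate
its own baseline) smoothed with a 0.5 s forward moving average matched to
the sharp-rise/slow-decay transient shape. Events are local maxima above
`max(min_amplitude, threshold_sd × MAD/0.6745)` with defaults
`min_amplitude = 0.2` ΔF/F0 and `threshold_sd = 3`, must rise by at least
the threshold above the minimum of the preceding refractory window (this
rejects noise bumps riding on the decay tail of an earlier event), and
are separated by `refractory_s = 1` s (closer peaks collapse to the
largest). Event time and amplitude are then read from the unsmoothed
detrended trace. There is no community-standard parameterization for
threshold-based spike detection, so every parameter is surfaced in the
function signature; the defaults were chosen so that detection is
reliable at the simulator's default signal-to-noise (the
suite verifies recall ≥ 0.95 and FDR ≤ 0.05 across an amplitude × noise
grid wherever amplitude ≥ 5× the noise sigma).

Synchrony: a synchronous event is a sliding window (default 0.5 s) in
which at least a `participation` fraction of all ROIs fire; overlapping
qualifying windows merge into one event timed at the median participant
spike (tie: earliest). The strict reading of "all ROIs" is
`participation = 1`; the default 0.8 tolerates single-cell detection
misses. The rate is monotone non-increasing in `participation`, which the
suite checks.

The NMDA/AMPA ratio reads |I(+40 mV)| at exactly onset + 20 ms (linear
interpolation between samples) over the peak |I(−70 mV)| within the event
window, validated against a closed-form biexponential oracle.

## Chromatin states

The atlas removes blacklisted peaks first, then pools, sorts, and
transitively merges peaks with gaps ≤ 500 bp (BED coordinates, 0-based
half-open; "within 500 bp" read as end-to-start gap). The construction is
idempotent and leaves all same-chromosome gaps > 500 bp — both properties
are asserted on randomized fixtures. Depth normalization scales each
sample to 10 M fragments and conserves within-sample ratios exactly.

Mark presence per (peak, stage) compares the replicate-mean normalized
signal to a per-mark threshold. Peak callers decide presence at the read
level against matched IgG controls, which a count matrix cannot
reproduce, so the default is an explicit count-level stand-in — 2× the
atlas-wide median of the mark — with an absolute per-mark threshold
available for users with calibrated data (e.g. IgG-derived). Transition labels are assigned in
fixed precedence: `bivalent_resolving` (K4me3 ∧ K27me3 at the precursor
stage; K27ac ∧ ¬K27me3 in neurons), `active_gaining` (quiet precursor;
K4me3 ∧ K27ac neuron), `immature_open` (active precursor; quiet neuron),
`stable` (identical presence pattern), else `other`.

Peak-to-gene annotation assigns intragenic peaks to the overlapped gene
(ties: nearest TSS from the peak midpoint, then lexicographic gene id)
and intergenic peaks to the nearest same-chromosome TSS by midpoint
distance. The midpoint anchor and the tie-breaks are conventions fixed
by this package and verified against an all-pairs brute-force oracle.

Differential peaks (union of pairwise contrasts at FDR ≤ 0.05, computed
by the same Welch stand-in applied directly to the depth-normalized
matrix — re-deriving per-million scaling from in-atlas sums would
re-normalize by atlas composition) are z-scored per peak and clustered by
Ward linkage (`ward.D2` on Euclidean distance, the Ward criterion) cut at
k, or by the redundancy-stopped k-means. Cluster expression profiles
z-score each gene across timepoint means and average over the cluster's
annotated, differentially expressed genes; flat genes are excluded with a
warning.

## Motif enrichment

For motif m and peak group g: N atlas peaks, K carrying m, n group peaks,
k carrying m; p = P(X ≥ k) upper-tail hypergeometric (enrichment only —
depletion is not tested, matching the procedure's use), odds ratio =
(k/n)/(K/N), BH across motifs within the group (the package's choice of
multiple-testing correction). The
filter keeps odds ratio ≥ 1.2 (inclusive) and ≥ 1 RPKM (inclusive) for at
least one associated factor at any neuronal timepoint, ranked by odds
ratio, ties by p then motif id, and is monotone in both thresholds.
Rank-based (Kolmogorov–Smirnov) enrichment variants are deliberately out
of scope: without a fixed choice of ranking statistic they are not
well-defined, and the hypergeometric test covers the set-membership
question this package asks.

## What the simulators emulate — and what they do not

Every simulator returns its dataset together with the planted truth, and
is bit-reproducible for a fixed seed (a single seeded stream per
simulator; the seed is recorded in the truth object).

**Expression** (`simulate_expression_timecourse`): negative-binomial
counts, one shared dispersion (default 0.05), 6 timepoints × 2 arms × 3
replicates, 2,000 genes by default with 10% planted monotone-up and 10%
monotone-down at 1 log2 unit per neuronal transition. Planted trends are
*centered on the baseline* — up genes start 1.5 effect-units below it and
cross mid-course, down genes mirrored — so the total library mass stays
balanced across timepoints. An uncentered design would shift per-million
scaling for every flat gene and manufacture spurious endpoint fold
changes; the centered design is also the biologically natural picture
(maturation genes start low and rise, progenitor genes start high and
fall). The flat baseline is `base_mean_log2 = 8` (≈256 counts), a
well-measured gene, chosen so a one-log2FC step is detectable by a
Welch test at n = 3. Not emulated: gene-specific dispersion, length
bias, batch effects, treatment-specific programmes (both arms share
means), or read-level sampling — so passing recovery tests demonstrates
correctness of the classification logic at realistic effect sizes, not
robustness to every RNA-seq artifact.

**Calcium** (`simulate_calcium_traces`): private Poisson events per ROI
plus network events joined with a participation probability; each event
is an instantaneous jump (amplitude normal truncated at zero, default
1.0 ± 0.2 ΔF/F0) decaying exponentially (τ = 2 s) on a constant baseline
with additive Gaussian noise. Two deliberate discretizations make
"planted spike count" well-defined: event times snap to the frame grid
(so the planted amplitude is realized exactly at a sampled frame), and a
per-ROI refractory (`min_separation_s`, default 1 s, the detector's
refractory) thins events closer than the recording can resolve. Gaussian
additive noise is an assumption, as are the absence of drift, bleaching,
and indicator-kinetics rise time. Defaults (3 min at 5 Hz) match the recording design the
package targets.

**Chromatin** (`simulate_chromatin_landscape`): non-overlapping peaks
(gaps > 500 bp, so the atlas is a fixed point of `build_peak_atlas`),
exact state allocation (default 15% bivalent-resolving, 15%
active-gaining, 15% immature-open, 55% stable-quiet), Poisson fragment
counts at `signal_high = 100` / `signal_low = 5` scaled to library sizes.
Making `stable` background-low keeps every mark's atlas-wide median at
background level, so the 2×-median presence threshold separates high from
low cleanly; a landscape in which most peaks carried a mark would need an
explicit threshold instead. Not emulated: overlapping peak calls (atlas
merging is stress-tested on separate randomized fixtures), fragment-length
effects, IgG background structure.

**Motifs** (`simulate_motif_annotation`): Bernoulli background presence
(p0 = 0.2) with planted (group, motif) pairs present at
min(1, factor × p0). `simulate_gene_models` is a synthetic gene-model
builder that co-locates bivalent-resolving peaks with planted mono-up
genes (and immature-open with mono-down), so the chromatin→expression
intersection is testable end to end; it is plumbing for the synthetic
study, not a model of real gene architecture.

## Problem sizes and determinism

The test suite and the acceptance script run the synthetic study at
2,000 genes / 1,000–2,000 peaks / 6–12 ROIs × 3 min, sizes at which every
stage completes in seconds while leaving recovery estimates with
standard errors of a few percent. The full default pipeline
(`run_pipeline`) is deterministic given its seed: stage seeds derive from
the master seed, all writers emit plain text, and the summary JSON is
byte-identical across runs — asserted in the suite.

## Known limitations

- The Welch-on-log2 differential stand-in is underpowered relative to
  negative-binomial models at n = 3 and small effects; strict-mode calls
  in particular are conservative (intermediate transitions often miss
  FDR ≤ 0.05). Use external differential tables for real data.
- The mark-presence threshold is count-level, not read-level; with real
  CUT&RUN data supply per-mark thresholds derived from IgG controls.
- Spike detection assumes sharp-rise transients; slow-rising indicators
  would need a different matched filter.
- The maturation score is only comparable within one embedding; scores
  from different gene selections or normalizations are not on a common
  scale.
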