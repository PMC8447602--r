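---
title: "Statistical methods behind apmsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind apmsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`apmsflow` analyzes affinity-purification mass-spectrometry (AP-MS)
label-free quantification (LFQ) data: it decides which proteins genuinely
interact with a tagged bait, quantifies how interactions and
posttranslational modifications (PTMs) move over an activation time course,
and groups co-regulated features. This vignette explains the models and the
choices behind each stage, what the synthetic-data generator does and does
not emulate, and the package's numerical conventions.

## Data model and containers

The central objects are `ProteinQuant` (raw linear LFQ intensities, one row
per protein group, zero meaning "not quantified") and `LogIntensities`
(log2 intensities with two aligned logical masks, `missing` for cells that
were never quantified and `imputed` for cells filled in afterwards). Both
extend `SummarizedExperiment`, so the sample annotation — bait identity,
condition, time point in minutes, replicate — travels in `colData` and is
never re-derived from file order. Keeping the two masks separate is what
lets later stages distinguish *observed* evidence from *imputed*
pseudo-data: interaction calls require a minimum number of observed values,
and the PTM pipeline refuses imputed values entirely.

## Identification filtering and valid values

Protein groups flagged as decoy (reverse), contaminant or
only-identified-by-site are removed, as are groups identified by a single
peptide (`min_peptides = 2`, i.e. "more than one" razor + unique peptide).
A feature is quantifiable if it has valid values in strictly more than 60%
of the replicates of at least one group; groups default to bait cell lines
(`group_by = "bait_id"`) and the threshold is applied as a strict
inequality, so 3 of 5 replicates (exactly 60%) does not qualify. Both
filters are idempotent and only ever shrink the feature set.

## Detection-limit imputation

LFQ dropout is missing-not-at-random: the probability of a missing value
rises as the true abundance approaches the detection limit. Missing cells
are therefore drawn, per sample, from a Gaussian centred below the observed
intensities of that sample:

$$x_{\text{imputed}} \sim N(m - d\,s,\ (w\,s)^2), \qquad d = 1.8,\ w = 0.3,$$

with $m$ and $s$ the observed mean and standard deviation of the sample
(log2 scale). Imputation is per sample because detection limits differ
between runs. The width (0.3) and downshift (1.8) are the standard
parameterization of this procedure in AP-MS practice and are exposed as
arguments. The generator is an explicit seeded stream
(`imputeMissing(..., seed = )`): identical seeds give bit-identical
matrices, and global RNG state is restored afterwards.

## Control groups

Baits are not tested against a universal control but against the other
pull-downs that share their background binder population. Sample profiles
are correlated (Pearson, over cells quantified in both samples of a pair,
requiring at least 10 shared cells), and average-linkage hierarchical
clustering on $1 - r$ is cut into `n_groups` control groups. The number of
groups is a design decision of the experimenter; when set to `"auto"` the
cut maximizing the mean silhouette width over 2..min(6, #baits − 1) is
used. Every group must contain at least two distinct baits, otherwise a
bait would have no complement to be tested against.

## Interactor calling and permutation FDR

For each bait, every feature is tested with a two-sided two-sample
Student's *t*-test (pooled variance — the classical two-sample default of
the analysis environment this workflow mirrors; no variance moderation is
applied) of the bait's samples against the *complement*, all other samples
in the bait's control group. The effect is reported as bait mean minus
complement mean (log2), and `fold_enrichment = 2^difference` exactly.

The FDR is estimated by permutation: sample labels are randomly reassigned
between the two groups (group sizes preserved; 250 randomizations by
default) and all |t| recomputed. For a feature with observed magnitude $c$,

$$q = \min\!\left(1,\ \frac{\text{mean permuted } \#\{|t| \ge c\}}
                         {\text{observed } \#\{|t| \ge c\}}\right),$$

then enforced monotone non-increasing in |t|. Two conventions matter here:

* **The unpermuted labeling is excluded.** A relabeling identical to the
  observed grouping (or its mirror image when group sizes are equal) is not
  a permutation of it; including it would put a hard floor of roughly
  $2/\binom{n}{n_1}$ under every q-value and make small designs (3 vs 3)
  incapable of ever reaching q below 0.1. With the exclusion, a clear top
  hit can reach $q = 0$, and on small designs the estimator is computed
  exhaustively: whenever the number of distinct relabelings is at most
  `n_permutations`, all of them are enumerated, making the estimate exact
  and seed-independent. Sampled relabelings are otherwise drawn without
  enforcing uniqueness.
* **Degenerate rows.** The permutation pass computes group variances from
  one-pass sums for speed; on (near-)constant rows these cancel
  catastrophically, so degeneracy is detected at a relative tolerance
  ($10^{-7}$ of the row's RMS magnitude) rather than at exact zero, and
  resolved as $|t| = 0$ when the means agree and $|t| = \infty$ when they
  do not — matching the limit behaviour of the statistic.

A feature is a significant interactor iff $q < 0.01$, linear fold
enrichment strictly exceeds 2, and at least `min_valid` *observed* values
support it in the bait group. The observed-value requirement exists because
imputed cells are pseudo-data: without it, a feature missing everywhere
and imputed low in the complement could masquerade as an interactor. The
default `min_valid = 10` presumes bait groups of ~16 samples (four time
points in quadruplicate); on a plain 4-replicate design the analogous
requirement is 3 of 4 (the >60% rule), which is what the packaged benchmark
uses. Results are ranked by ascending q, then descending difference, ties
broken lexicographically by protein id, so output order is deterministic.

Whole-proteome comparisons (`wholeProteomeDiff()`) reuse the same machinery
with the conventional whole-proteome thresholds: FDR < 0.05, enrichment
> 2, minimum two valid values.

## Dynamics: normalizations and per-time-point tests

Prey LFQ intensities are divided by the bait's LFQ intensity in the same
sample, on the linear scale. This cancels any per-sample loading factor
exactly (the operation is scale-equivariant, which the tests assert), at
the price of propagating bait missingness: a sample without a bait value
yields no normalized values and is flagged. PTM site intensities (peptide
rows first summed per site) are divided by their protein's intensity, which
cancels abundance changes and leaves an occupancy-like ratio. Sites must
have valid ratios in at least 3 replicates of at least one time point; no
imputation is ever applied on this path.

Each activated time point is compared against time 0 with a two-sided
Student's *t*-test. Tests run on log2 ratios by default — raw ratios are
multiplicatively skewed, and the log makes up- and down-regulation
symmetric — with `log_ratios = FALSE` available for the raw scale. In line
with the per-test convention of this workflow no multiple-testing
correction is applied across time points or features at the default
`alpha = 0.05`; a feature is dynamic if any time point is significant.

## Co-regulation clustering

Features with at least 70% valid normalized values are reduced to
per-time-point medians and z-scored across time points (mean 0, sd 1 per
feature). The order is normalize → median → z-score: the validity filter is
applied to the per-sample values feeding the medians, not to the medians
themselves. Constant profiles have no defined z-score and are dropped with
a warning. Profiles are clustered by average-linkage hierarchical
clustering on $1 - r$ (Pearson) and the tree is cut into `k = 7` clusters
by default; `k` is a user decision, not estimated. Average linkage is the
common default with correlation distances; the clustering is deterministic
and invariant to feature order and to affine rescaling of any raw profile.
Cluster labels are renumbered by descending size, then earliest peak time,
so labels are reproducible. Cluster summaries report the per-time-point
median with a bootstrap 95% confidence band (500 resamples, seeded) and a
loess curve (`y ~ x`, span 0.75, degree 1) through all member points;
degree 1 keeps the fit defined for small clusters, and if the smoother
cannot be fitted at all the median curve is reported in its place.

## Networks

Significant (bait, prey) pairs form an undirected graph; preys called by
several baits appear once, connecting the pull-downs. Known-interaction
annotation matches each calling (bait, prey) pair, orientation-insensitive,
against an offline two-column reference list — deliberately a file, not a
live database query, so builds and tests are hermetic. Annotation never
changes topology and is idempotent. Exports: plain edge-list TSV and
GraphML.

## The synthetic-data generator

The generator emulates the statistical structure the analysis relies on:

* a shared log-normal background (per-protein baseline
  $N(24, 2^2)$ log2 units) common to all pull-downs, which induces the
  high inter-sample background correlation (> 0.9) typical of reproducible
  AP-MS panels, plus additive replicate noise (sd 0.3 log2 units);
* bait self-enrichment (+6 log2) and spiked true interactors (+3 log2,
  i.e. 8-fold) confined to the owning bait's samples;
* logistic intensity-dependent dropout,
  $P(\text{missing}) = \text{logit}^{-1}((\text{mid} - x)\cdot k)$ with
  midpoint 20 and slope 1, reproducing the left-censored missingness the
  imputation assumes;
* time-course profile classes (`early_up`, `late_up`, `down`, `flat`) as
  multiplicative trajectories with peak amplitude 2 log2 units (4-fold),
  and PTM sites generated as protein intensity × occupancy trajectory ×
  noise.

The defaults (20 baits × 4 replicates, 2,000 background proteins, 15
interactors per bait) are the package's benchmark conditions, chosen once
to mirror a realistic panel — a few thousand quantified proteins per run
and a median on the order of 15 interactors per bait — at a size a desk
machine handles in seconds per dataset. What the generator does **not**
emulate: peptide-level identification, ratio compression, shared peptides
between protein groups, batch effects, and correlated (complex-level)
interactor intensities. Green benchmarks therefore demonstrate that the
statistics behave as designed under the assumed model, not that any
particular biological dataset will reach the same recall.

## Benchmark results computed by the package

`benchmarkInteractorCalling()` runs the generator-to-calls pipeline over a
set of seeds and scores against truth. Under the default conditions the
acceptance suite checks that the mean empirical false-discovery proportion
over 20 seeds stays at or below the nominal 0.01 and that recall of spiked
interactors is at least 0.95; `scripts/acceptance.R` recomputes the same
quantities from scratch, plus the realized imputation downshift and width
on a 100,000-cell column. Problem sizes in the tests (hundreds of features
for oracle comparisons, the full default panel for the benchmark) were
chosen so the whole suite runs in a couple of minutes.

## Known limitations

* Student's pooled-variance *t* without moderation is faithful to the
  mirrored workflow but less powerful than moderated statistics at very
  low replicate numbers.
* The SAM-style q estimator is conservative when a control group contains
  few baits, because the complement's truly-enriched rows inflate the
  permuted tail; with panels of ≥ 10 baits per group the effect is
  negligible.
* PTM quantification assumes site tables with per-sample intensities;
  evidence-level aggregation is out of scope, and multiple peptide rows
  per site are summed rather than modeled.
* The bait's own row is kept in its test and typically tops the ranking;
  it is not removed automatically.
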