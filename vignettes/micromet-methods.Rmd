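---
title: "Methods: microbe-metabolite co-occurrence networks with micromet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbe-metabolite co-occurrence networks with micromet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromet)
```

## The analysis

micromet implements an integrative analysis of paired gut microbiome and
fecal metabolome profiles across experimental groups, patterned on a
four-arm murine design: chow or Western diet, each with or without Gulf
War Illness-related chemical exposure (Chow, Chow+GWI, WD, WD+GWI). The
pipeline has five stages:

1. **Group-wise univariate statistics.** Exact Mann-Whitney tests per
   feature, median-scaled fold changes, volcano statistics and log-scale
   box-plot summaries.
2. **Diversity and ordination.** Shannon alpha diversity, Bray-Curtis
   dissimilarities, and PCA of log-standardized metabolite profiles.
3. **Three correlation layers per group.** SparCC for microbe-microbe
   (compositional data), Spearman for metabolite-metabolite, and
   cross-modal Spearman between the two, each with two-sided p-values.
4. **Per-group heterogeneous networks.** Signed, weighted two-mode graphs
   whose edges are significant correlations; triad-ablation (ATria)
   centrality ranking; KEGG-supported edge annotation; identification of
   network-specific metabolites across groups.
5. **A synthetic data generator** with planted ground truth, so every
   stage is testable end to end without access to animal data.

## Statistical components

### Exact Mann-Whitney

For group sizes with `nA + nB <= 14` — which covers the 6 vs 6 design the
package targets — the two-sided p-value is exact: the U statistic (average
ranks under ties) is enumerated over all `choose(nA + nB, nA)` labelings
of the observed ranks, and `p = min(1, 2 * min(P(U <= u), P(U >= u)))`.
This conditions on the observed tie pattern, so tied data are handled
without approximation. Larger designs switch to the normal approximation
with tie and continuity correction. Two consequences matter for
interpretation:

* the smallest attainable two-sided p at 6 vs 6 is `2/924 ≈ 0.0022`, so
  the two-star (`p < 0.01`) convention is attainable but three-star
  conventions would not be;
* the test is discretely conservative at this size: its achieved level at
  nominal 0.05 is `2 * 19/924 ≈ 0.041`. Calibration checks of the nominal
  level are therefore run at n = 20 per group, where the null p
  distribution is dense enough for 0.05 to be the right reference; at
  n = 6 the meaningful check is against the enumerated achieved level.

### Fold changes and normalization

There is no single community convention for metabolite fold changes, so
the package adopts the mass-spectrometry panel convention: each feature is
divided by its across-sample median (median scaling, so every feature's
median is 1), and the fold change is the ratio of scaled group means,
reported as log2. Zero intensities are imputed with half the feature's
smallest positive value (standard minimum imputation for MS data;
configurable). Features whose denominator is zero are flagged rather than
given a fabricated value. No multiple-testing correction is applied by
default, matching per-feature `p < 0.05` usage; Benjamini-Hochberg is
available behind a flag.

### Spearman with exact small-sample p-values

Spearman rho is the Pearson correlation of average ranks. For `n <= 7`
the two-sided p is exact by full enumeration of all `n!` permutations,
`p = P(|rho_perm| >= |rho_obs|)`, conditioning on both tie patterns; the
permutation null depends only on the two rank multisets, so the null is
cached per tie-signature pair, which makes whole-table layers fast.
At the n = 6 group size the enumerated significance floor is
`|rho| = 0.8857` (`p = 0.0333`): no pair below it can ever be
significant, a structural property of per-group networks at this design
size. Larger n uses the t approximation; a seeded Monte-Carlo permutation
mode exists for checking it.

The cross-modal layer ranks each modality's table separately and
correlates the two rank sets; this is mathematically the same as pairwise
Spearman, and is kept as a distinct staged operation because the two
tables live on different scales (relative abundances vs ion counts) and
are validated to cover identical samples.

### SparCC

Relative abundances are compositional: closure induces spurious negative
correlation, so naive Pearson on fractions is biased. SparCC estimates
correlations of the latent basis abundances from log-ratio variances
`t_ij = var(log(x_i/x_j))`. Under the sparsity approximation the basis
log-variances solve the linear system
`sum_j t_ij = (d - 2) w_i + sum_j w_j`, and
`rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped to [-1, 1].
Strong pairs violate the approximation, so the largest |rho| above an
exclusion threshold (default 0.1) is iteratively removed from the system
(up to 10 rounds), never letting a species fall below two included
partners. Zeros are resolved by per-sample Dirichlet resampling of
pseudo-counts (counts + 1); the reported rho is the median over 20
resamplings. Input columns are always renormalized to fractions and
re-gridded as pseudo-counts (x 1e4, rounded) first, which makes the
estimate invariant to per-sample sequencing depth. Two-sided p-values
come from a seeded permutation null (default 100 rounds) that shuffles
every species' samples independently; a pair whose basis variance solves
non-positive is reported as undefined rather than fabricated. Only the
significance level (p = 0.05) is fixed by convention; the resampling,
iteration and exclusion constants follow the original SparCC method's
defaults and are all configurable.

### Network assembly and admission

For each group, correlations are computed within that group's samples
only — four separate networks require per-group estimation. An edge is
admitted when `p <= 0.05` (uncorrected by default, matching common
per-pair usage in co-occurrence studies; layer-wise Benjamini-Hochberg
behind a flag),
its weight is the signed correlation, and a node exists exactly when it
has at least one admitted edge. Microbe nodes carry phylum and group-mean
relative abundance; metabolite nodes carry pathway annotation and
group-mean median-scaled intensity. KEGG support marks edges that are
positive *and* whose endpoints share a pathway identifier in the
user-supplied mapping; negative edges are never marked: pathway
co-membership is evidence for a positive association only. A metabolite is *network-specific* to a group
when it is a node in that group's network and in no other — the sets are
disjoint by construction, and each is reported with per-group mean
intensities so fold-change observations can be checked descriptively.

### ATria centrality

The ranking algorithm is reconstructed from the original Ablatio Triadum
description; micromet exposes the
internals as parameters so alternative readings can be tested. The pay of
node i is `|sum_j P_ij|`, where `P_ii = 1` and `P_ij` is the signed value
of largest magnitude among the direct edge `w_ij` and all two-step
products `w_ik * w_kj` (paths of length <= 2, the "triads"). Each round
extracts the argmax pay (ties broken by lexicographically smallest id,
for full determinism), then ablates the node, its incident edges, and
every edge closing a triangle with it, so later ranks are not paid twice
for the same triads; extraction stops when every remaining node is at its
self-pay of 1, and those nodes form an unranked residual. Two boundary
facts, confirmed against an independent brute-force pay calculator before
the implementation was written: on a star with saturated weights (+1 or
-1) *all* nodes tie, because each leaf collects the hub's pay through
two-paths of product +1 — the hub is then first by the tie rule alone —
while any |weight| < 1 makes the hub strictly first; and pay uses the
magnitude of the signed sum, so a strongly negative hub ranks as high as
a positive one ("villains" count).

### Layout

Visualization uses Fruchterman-Reingold with attraction along
positive-weight edges only (negative edges contribute no pull; repulsion
acts between all nodes), so positively correlated entities land near each
other. Coordinates are seeded and centred; layout is presentation-only
and nothing downstream depends on it beyond determinism.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the raw data types (no reads, no spectra):

* **Species**: a log-normal basis — per-species baseline log-means with
  spread `baseline_sd = 2` (a strongly uneven, dominance-structured
  community, as in real gut data) plus per-sample log-noise
  `noise_sd = 0.5` — multiplied by planted group effects, zero-masked,
  then closed to fractions. The pre-closure basis is kept as ground
  truth, so compositional-correction claims can be tested against known
  basis correlations.
* **Zeros**: a detection-limit model. Each cell is Bernoulli-masked with
  probability rising logistically (softness 0.5 log-units) as its basis
  value falls below the table-wide `sparsity` quantile (default 0.3).
  Rare taxa are therefore mostly zero while dominant taxa are always
  observed — the "mostly zero or near-zero" regime. A uniform random
  masking was rejected: zeroing high-abundance cells at random is not how
  detection limits behave, and it destroys rank correlations to the
  basis so thoroughly that no planted signal of any strength survives.
* **Metabolites**: log-normal ion-count-like intensities around
  `log(1e6)`, with planted group effects, and planted cross-modal links
  built as `rho * z_s + sqrt(1 - rho^2) * eps` against the standardized
  *pre-closure* log basis abundance of the linked species — so the
  compositional distortion of closure is deliberately part of what the
  correlation stages must overcome.
* **Calibration**: `noise_sd = 0.5` puts a planted two-fold change at
  ~2.8 residual SD, where the exact rank test at n = 6/group has ~98%
  power — the generator's planted-recovery guarantees require an effect
  size the design can actually detect, and the dispersion of the real
  data is unknown, so the default is chosen for testability.
* A planted species-species basis correlation (`species_links`) supports
  testing the compositional correlation stage directly.

Everything is a deterministic function of the seed; ground truth
round-trips through JSON exactly, and tables round-trip through TSV
exactly (doubles are serialized with 17 significant digits).

### What the generator does not emulate

Real taxonomic profiles have correlated taxa beyond planted pairs,
overdispersion beyond log-normal, batch structure, and compositional
zeros that are partly sampling artifacts; real metabolite panels have
heavy-tailed intensity distributions, missingness mechanisms tied to
chemistry, and correlated metabolite blocks. Passing tests therefore
demonstrate that the pipeline recovers structure *under its own model
assumptions* at desk scale — they do not certify performance on real
data, and results from any particular animal study can only be
reproduced with that study's own tables as input.

## Known limits of recovery

One end-to-end property deserves honesty: recovering a planted
cross-modal link as a *network-specific* metabolite across four groups
is structurally hard at desk scale. Under uncorrected `p <= 0.05`
admission, every metabolite acquires a chance edge in another group's
network with probability ≈ `1 - 0.95^40` per group, so specificity is
essentially never observed. Under layer-wise Benjamini-Hochberg
admission, the bar for a true cross-modal edge among 40 x 120 pairs is
a raw `p` of roughly `3e-5` (|rho| >= ~0.80 at n = 20) — but a planted
basis-level correlation of 0.9 caps at a Spearman of 0.891 (Gaussian
copula) even before compositional attenuation (a further x0.87-0.97
after closure). Per-link admission is therefore ~0.65 and joint
three-link specificity ~0.3 at the package's default community, with a
ceiling near 0.9 even for an ideal, distortion-free pipeline. The
package reports both sides of this honestly: edge recovery in the home
group's default network is essentially certain, while specificity
recovery is reported as measured. Practically, claims of
network-specificity on real 6-animal groups should be read as
descriptive, not inferential.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use the smallest sizes at
which the property under test is meaningful: 40 species x 120 metabolites
(the package default; the real panel is ~8x larger), 50-100 seeds for
Monte-Carlo rates, n = 200 samples for basis-correlation recovery, and
n = 20/group where approximation-regime behaviour is the point. Exact
enumeration cutoffs (14 observations for Mann-Whitney, 7 for Spearman)
are chosen so the four-arm 6/group design is always exact. Tolerances:
compositional closure to 1e-9; PCA reconstruction to 1e-8 (Frobenius);
rank-permutation p-values carry a 1e-9 guard against floating-point ties.
PCA signs are fixed by forcing each component's largest-magnitude loading
positive. Shannon diversity defaults to natural log (nats) with a base argument
for groups that report bits or dits.
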