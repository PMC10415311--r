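---
title: "Models and methods behind mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

mitonet implements a brain-wide mitochondrial phenotyping analysis: from raw
enzymatic and qPCR readouts to six mitochondrial features per brain area, and
from those features to mitochondria-based brain networks, their topological
characterization under stress, their validation against independent data
modalities, and their association with behavior. This vignette documents the
models, the tunable parameters, the numerical choices, and what the synthetic
data generator does and does not establish.

## Mitochondrial features and the MHI

Each site (17 brain areas, 5 peripheral tissues) is characterized by six
features: the enzymatic activities of respiratory-chain (RC) complexes I, II
and IV, citrate synthase (CS, a mitochondrial content marker), mtDNA density
(copies per unit tissue), and the mitochondrial health index

$$\mathrm{MHI} = \frac{CI + CII + CIV}{CS + \mathrm{mtDNA\ density} + 1}
\times 100,$$

computed on *mean-centered* features: each feature is divided by its
across-animal mean within the site, so the cohort-average animal sits at 1 on
every feature and scores exactly (1+1+1)/(1+1+1) × 100 = 100. The constant 1
in the denominator balances the three-term numerator against the two content
terms. Division (rather than subtraction) is the only centering under which
the worked example holds, and it makes MHI invariant to the measurement units
of any single feature — `compute_mhi()` is tested for exactly that
invariance.

Upstream QC follows the assay conventions:

* **Enzymatic activities** (`specific_activity()`): mean of duplicate
  absorbance slopes minus the non-specific (negative-control) slope, times
  the extinction/dilution factor; duplicates with CV above 10% are flagged.
  Plates are aligned by their positive controls
  (`normalize_plate()`): every activity is multiplied by
  `assay_reference / plate_control`. The source description of this factor
  ("1 divided by the z-scored positive control") is undefined when a plate's
  control equals the assay mean (z = 0, division by zero); the ratio-to-mean
  form implements the evident intent — a plate at the reference level has
  factor exactly 1 — and is verified by a round-trip test in which two
  plates reading the same samples at different control levels align after
  normalization.
* **mtDNA** (`ct_to_mtdnacn()`): triplicate Cts are averaged per amplicon;
  samples with mean Ct > 33 are excluded; if the triplicate CV exceeds 0.02
  the replicate farthest from the median is dropped; if the remaining CV
  exceeds 0.1 the sample is discarded. Then ΔCt = mean(nuclear) −
  mean(mito) and mtDNAcn = 2^ΔCt × 2.
* **mtDNA density** (`ct_to_mtdna_density()`): the published linearization
  `2^Ct / (1/10^-12)` *increases* with Ct, which is backwards for qPCR
  (more template → lower Ct). Both that verbatim form and a sign-corrected
  `2^(−Ct) × 10^12` are provided; the mode is recorded in the output and no
  silent correction is made.

## Behavioral composites

Four tests are scored (`behavior_zscore()`): open field (OFT), elevated plus
maze (EPM), novelty-suppressed feeding (NSF, latency right-censored at
600 s), and social interaction (SI). Each raw measure is z-scored across
animals and sign-flipped so that *higher always means more avoidant*: SI
ratio and SI-zone time, both OFT center measures, and EPM open-arm time are
inverted; corner measures and NSF latency are not. The composite is the mean
of the signed z-scores; missing tests stay missing, never imputed.

## Connectivity and the multi-slice networks

`feature_area_matrix()` builds the 102 × 102 (17 areas × 6 features) Pearson
correlation matrix across animals, pairwise-complete so that a cracked
section costs only its own entries; per-entry overlap counts are retained and
entries resting on fewer than 4 animals are dropped. `per_feature_slices()`
produces one 17 × 17 area slice per feature — the six-layer multilayer
network. Negative correlations are retained throughout; nothing is
thresholded.

Communities are found by maximizing the categorical multi-slice modularity

$$Q = \frac{1}{2\mu}\sum_{ijsr}\left[\left(A_{ijs} -
\gamma_s\frac{k_{is}k_{js}}{2m_s}\right)\delta_{sr} +
\delta_{ij}C_{jsr}\right]\delta(g_{is},g_{jr}),$$

with resolution γ = 1 on every slice and all-to-all identity coupling
C = ω = 0.1 between slices (robustness to ω in 0.05–0.2 is exposed via the
`omega` argument). Slice diagonals are zeroed before degrees are computed.
The optimizer (`optimize_communities()`) is a generalized Louvain on the
supra-modularity matrix: seed-shuffled single-vertex moves alternating with
community-level moves on the aggregated quotient, so the returned partition
is a local optimum under both; Q never decreases during the search. On small
problems it is tested against exhaustive enumeration of every node-layer
partition.

`consensus_communities()` repeats the optimization (paper-scale 1000 runs;
tests scale this down because strong structure converges identically),
summarizes co-assignment across runs × slices in a module allegiance matrix,
and iteratively re-clusters the allegiance matrix minus its mean off-diagonal
value (the permutation-expected co-assignment) until repeated clusterings
agree, capped at 50 iterations. Allegiance across runs × slices (rather than
slices only) is the default because it is the variant that makes the
1000-run ensemble meaningful.

With the default synthetic world at the study's size (27 animals), the
consensus is genuinely bistable between the planted three networks and a
two-network merge of the sub-cortical networks — the per-entry sampling noise
of a correlation at n ≈ 27 is ~0.2. The package does not hide this: the
pipeline test accepts either outcome, and exact recovery is asserted in the
strong-signal world (within-block r = 0.9, 20 animals per group) where it
holds in ≥ 95% of seeds.

## Mapper and the participation coefficient

Stress-induced recalibration is analyzed on delta matrices
(`delta_matrix()`): 102 rows (area × feature) by one column per stressed
animal, each entry the animal's value minus the naive-group mean; missing
cells are linearly interpolated within group along the row order.

The Mapper filter (`mapper_embed()`) is a deterministic spectral
neighborhood embedding (Laplacian eigenmaps with locally adaptive Gaussian
bandwidth, k = 8 neighbors): a nonlinear, neighborhood-preserving 2-D
projection. The contract the rest of the pipeline relies on — well-separated
clusters stay linearly separable in the embedding — is tested directly, and
the filter is pluggable (`build_mapper()` takes any coordinate matrix).
Determinism comes free: the eigendecomposition needs no randomness, and the
config seed exists only for stochastic replacement filters.

The cover is an 8 × 8 grid (64 bins) with 70% overlap, each base interval
expanded by `overlap × width/2` on both sides (49 and 81 bins behave
similarly and are one argument away). Within each bin, rows are clustered on
their *original* high-dimensional values by single linkage with the classic
edge-length histogram gap heuristic: 10 histogram bins over [0, max
distance], cut at the first empty bin *after* the first occupied one (the
qualifier matters — without it a diffuse cloud shatters into singletons).
Every non-empty cluster is a node; nodes sharing a row are linked.

Node-level segregation/integration is quantified by the participation
coefficient $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$, with node communities
assigned by majority area label of member rows (ties to the lowest label
index), isolated nodes scored 0, and the graph value the mean over
non-isolated nodes. The group contrast is also reported as the relative
change (PC_b − PC_a)/PC_b.

Significance uses phase-randomized surrogates (`phase_randomized_null()`):
each group's delta matrix is Fourier-transformed along the 102-row
dimension, one shared random phase vector is applied to every column, and
the inverse transform yields surrogates that preserve the cross-mouse
covariance exactly (verified to machine precision) while destroying
consistent regional structure. The row sequence is used as the
randomization axis; per-area blocks would be an alternative, but the choice
only matters through the null's regional smoothness and the row-sequence
variant is the simpler, documented one. Two-sided p-values compare the
observed PC difference against the surrogate distribution.

## Cross-modal validation

`align_partition()` maps the 17-area partition onto matrices from atlases
that merge areas (dorsal + ventral dentate gyrus → DG); a merged label
inherits its members' community and errors if they disagree.
`strength_fraction()` (within-community weight over total weight) and
`modularity_q()` (weighted Newman modularity) quantify partition quality in
the foreign matrix; `permutation_test()` shuffles the area → community
assignment 10,000 times (size-preserving, the stricter null) and reports the
one-sided enrichment p-value with the standard +1 correction. Negative
co-expression values enter as-is by default, with an explicit clipping
option.

## Behavior association

`mito_behavior_panel()` computes Spearman correlations (average-rank ties)
for every (area, feature, test) triple with pairwise-complete animals, and
flags discoveries by Benjamini–Hochberg at q = 0.01 across the whole panel
— the analysis this emulates realized p < 0.002 at that FDR, and the
realized cutoff is attached rather than hard-coded.
`network_average_correlation()` averages standardized (area, feature) values
over a network per animal (standardization first, so no feature dominates by
scale) and correlates with a behavioral composite; Spearman and Pearson are
both reported, with r², and the single-predictor sample-size-adjusted
r² = 1 − (1 − r²)(n − 1)/(n − 2), computed from the Pearson estimate.

## Transcriptional mitotypes

From an areas × genes expression table restricted to mitochondrially
localized genes, `pathway_scores()` rescales each gene across areas to mean
100 and SD 10 and averages member genes per pathway (MitoCarta-style
annotations); `rank_pathways()` orders pathways by
log2(mean network-1 score / mean other-networks score);
`mitotype_ratio()` forms per-area ratios of two pathway scores;
`cluster_and_project()` gives the ward.D2/Euclidean dendrogram order and a
3-component PCA. Genes with boundary log2 fold differences of exactly ±1
are *included* in the over/under lists ("at least" a factor of 2). Both raw
and per-pathway-standardized clustering modes exist because the reference
analysis does not state which was used.

## The synthetic cohort generator

`generate_cohort()` emulates the study's structure: 27 animals in four
groups (11 naive, 5 chronic corticosterone, 6 social defeat, 5
defeat-recovered; any counts ≥ 3 are accepted), 17 brain areas + 5 tissues,
and the five primary features sampled from a latent-factor model

$$x_{a,i,f} = \mu_{a,f}\,\bigl(1 + g_a\,\mathrm{cv} +
\mathrm{cv}\,(\alpha F_{b(a),i} + \beta G_i + \sigma H_{a,i} +
\varphi\,\varepsilon)\bigr),$$

with one global brain factor G, one factor per planted community F, one per
site H, and feature-level noise. Variance shares are solved from three
targets: within-block inter-area correlation (default 0.45), between-block
correlation (0.09), and within-area cross-feature correlation (0.70). With
the planted 6/7/4 blocks these defaults imply a mean brain-wide coupling of
0.20, matching the emulation target of ~0.2. The between-animal coefficient
of variation is 0.36 for brain and 0.25 for periphery; peripheral tissues
get independent factors (brain–tissue coupling ≈ 0). Group shifts are
applied on the Hedges-g scale per area: corticosterone raises ~60% of areas
(default +0.35 g), social defeat lowers ~82% (−0.5 g), recovered animals
retain 20% of the defeat shift. MHI is *computed* from the sampled features
via `compute_mhi()`, never sampled. Missingness removes whole
(animal, area) sites (cracked-section losses, default 3%). Behavior scores
are coupled to the standardized network-1 feature mean with signed defaults
(OFT 0.40, EPM 0.70, NSF 0.10, SI −0.69, the network-level correlations the
study reports); NSF is emitted as a latency right-censored at 600 s; test
availability follows the study arms (SI with the defeat arm, EPM/NSF with
the corticosterone arm, OFT for everyone).

Per-area baseline levels are order-of-magnitude placeholders (the real
per-area means are not published); nothing downstream depends on them
because every stage works on correlations, ranks, or standardized values.

**What a green test does and does not establish.** The generator reproduces
the correlation geometry, group shifts, missingness pattern and coupling
structure the analysis assumes — so green tests establish that the pipeline
recovers structure it is designed to detect, with calibrated nulls. It does
not emulate assay-plate batch effects, heavy-tailed measurement error,
spatial autocorrelation between neighboring punches, or any real biological
heterogeneity beyond the latent-factor model, so green tests are not
evidence about those.

## Numerical choices and limitations

* Permutation p-values use the +1-corrected estimator, bounded below by
  1/(n_perm + 1); defaults are reduced (2000/200/200) with paper-scale
  counts (10,000/1000/1000) behind `paper_scale = TRUE`.
* Louvain tie-breaks go to the lowest community label; sweep order is the
  only seeded randomness.
* The consensus re-clustering subtracts the mean off-diagonal allegiance as
  the permutation-null expectation; a degenerate all-equal allegiance
  converges in one iteration.
* Hedges g uses the J small-sample correction with the asymptotic CI; the
  Gaussian fit in `distribution_test()` is maximum likelihood (divisor n).
* qPCR triplet repair drops the replicate farthest from the median —
  "outliers removed where appropriate" made concrete.
* Configuration serializes to JSON (no YAML parser in the supported stack).
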