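# mitonet

Brain-wide mitochondrial phenotyping and mitochondria-based brain networks.

Mitochondrial energy transformation capacity varies widely between brain
areas and between animals, and that variation is behaviorally meaningful.
`mitonet` is an R toolkit for the full analysis chain used to study this in
a heterogeneous mouse cohort (naive, chronic corticosterone, chronic social
defeat, and defeat-recovered animals) profiled across 17 brain areas and 5
peripheral tissues:

* **Assay processing** — duplicate-slope enzymatic activities (CI, CII,
  CIV, CS) with CV-based QC and plate normalization; triplicate-qPCR mtDNA
  copy number (`mtDNAcn = 2^ΔCt × 2` with the Ct > 33 exclusion and
  triplicate-repair ladder) and mtDNA density; the mitochondrial health
  index `MHI = (CI + CII + CIV)/(CS + mtDNA density + 1) × 100` on
  mean-centered features, so the cohort-average animal scores exactly 100.
* **Behavioral composites** — signed z-score composites for OFT, EPM, NSF
  (latency censored at 600 s) and SI, oriented so higher = more anxious.
* **Connectivity** — 102 × 102 (area × feature) Pearson matrices across
  animals, per-feature 17 × 17 slices, nodal degree, and a within- vs
  between-area permutation test.
* **Mapper + participation coefficient** — a topological shape graph of
  stress-vs-naive delta matrices (2-D neighborhood-embedding filter, 8 × 8
  cover with 70% overlap, single-linkage partial clustering), quantified by
  the participation coefficient `P_i = 1 − Σ_s (κ_is/k_i)²` and tested
  against covariance-preserving phase-randomized surrogates.
* **Multi-slice community detection** — categorical multilayer modularity
  (γ = 1, ω = 0.1) over the six feature slices, maximized by a generalized
  Louvain, with module allegiance and iterative consensus clustering to
  define the mito-based brain networks.
* **Cross-modal validation** — strength fraction and modularity of a
  partition in independent gene co-expression / structural connectome
  matrices, with size-preserving label permutation (10,000 shuffles).
* **Behavior association** — Spearman panels with BH-FDR flags, Gaussian
  distribution tests, exact binomial direction tests, and network-averaged
  mito-behavior correlations with adjusted r².
* **Mitotypes** — MitoCarta-style pathway scores (genes rescaled to mean
  100, SD 10 across areas), network fold rankings, mitotype ratios, and
  ward.D2/PCA summaries.
* **Synthetic cohorts** — a latent-factor generator that plants the
  3-network block structure, the ~0.2 mean brain coupling, the 36%/25%
  between-animal CVs, stressor effect directions, behavior coupling, and
  site-level missingness, so the whole pipeline is testable offline.

## Worked example

```r
library(mitonet)

co <- generate_cohort(synthetic_config(seed = 1))
co
#> <mito_cohort> 27 animals, 22 sites, 6 features
#>   groups: cort=5, csds=6, csds_rec=5, naive=11
#>   missing site cells: 21

slices <- per_feature_slices(co)
part <- consensus_communities(slices, n_runs = 200, seed = 1)
part
#> <partition> 17 areas in 3 communities
#>   1 : mOFC, mPFC, CPu, NAc, M1, V1
#>   2 : Hypoth, Amyg, SN, PAG
#>   3 : Thal, DGd, CA3, VTA, DGv, Cereb, VN
```

The consensus recovers the planted cortico-striatal network (1), the limbic
network (2) and the salience/navigation network (3). How well does the
cortico-striatal network's pooled mitochondrial signal predict anxiety-like
behavior on the elevated plus maze?

```r
net1 <- network_average_correlation(co, part, test = "EPM",
                                    network = unclass(part)[["NAc"]])
sprintf("Pearson r = %.2f, r2 = %.2f, adjusted r2 = %.2f (n = %d)",
        net1$r_pearson, net1$r_squared, net1$adj_r_squared, net1$n)
#> "Pearson r = 0.74, r2 = 0.55, adjusted r2 = 0.51 (n = 16)"
```

The generator plants an EPM coupling of 0.7, and the recovered correlation
(0.74 here; 0.69 on average over seeds) reflects it: network-1 mitochondrial
features explain about half of the between-animal variance in the composite
EPM score. The Mapper contrast of the two stressors:

```r
pr <- phase_randomized_null(delta_matrix(co, "cort"),
                            delta_matrix(co, "csds"),
                            n_null = 200, seed = 1)
sprintf("mean PC: CORT %.3f vs CSDS %.3f (relative change %.0f%%), p = %.3f",
        pr$pc_a, pr$pc_b, 100 * pr$relative_change, pr$p)
#> "mean PC: CORT 0.218 vs CSDS 0.343 (relative change 36%), p = 0.100"
```

Corticosterone produces area-specific (segregated, lower participation
coefficient) recalibrations while social defeat shifts areas coherently
(integrated, higher PC); on this single synthetic cohort the direction
matches but the phase-randomized null is not significant at n = 27 — the
planted-signal tests in `tests/testthat/test-acceptance.R` show where the
contrast is reliably detected. And the MHI worked example:

```r
compute_mhi(rbind(a = c(CI = 2, CII = 1, CIV = 4, CS = 8,  mtdna_density = 0.5),
                  b = c(CI = 4, CII = 2, CIV = 8, CS = 16, mtdna_density = 1.5),
                  c = c(CI = 3, CII = 1.5, CIV = 6, CS = 12, mtdna_density = 1)))
#>      a      b      c
#>  92.31 104.35 100.00
```

Animal `c` sits at the across-animal mean of every feature and scores
exactly 100.

## Command line

```sh
Rscript inst/cli/mitonet.R simulate   --out out --seed 1
Rscript inst/cli/mitonet.R multislice --out out --n-runs 200 --seed 1
Rscript inst/cli/mitonet.R run-all    --out out --seed 1   # full pipeline
```

Subcommands: `simulate`, `connect`, `mapper`, `multislice`, `crossmodal`,
`behavior`, `mitotype`, `run-all`; paper-scale permutation counts via
`--paper-scale`.

## Vignette

`vignettes/mitonet-methods.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, numerical choices, and known
limitations.
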