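# clonofate

Clonal fate-bias analysis for paired single-cell RNA-seq + single-cell
TCR-seq data.

When transcriptomes and TCR clonotypes are measured in the same cells, each
expanded clone — the progeny of one naive T cell — can be placed on the
transcriptional manifold and scored for fate bias: does it commit to a
T<sub>H</sub>1 or T<sub>FH</sub> effector fate, or spread across fates?
`clonofate` implements the full analysis as a tested R package plus a set of
numbered analysis drivers, exercised end to end on synthetic cohorts that
emulate the statistical structure of real antigen-specific T cell data.

## The statistic at the core

From PCA coordinates, an adaptive Gaussian-kernel kNN graph (k = 30, with
bandwidth σ<sub>i</sub> set at the ka = 10th neighbour) yields the
row-stochastic diffusion operator *P*, whose row *A<sub>i</sub>* is cell
*i*'s unit-normalized local neighbourhood. For a clonotype *c* with
*n<sub>c</sub>* cells, its **neighbourhood weight vector** is

> w_c = (1 / n_c) Σ_{i ∈ c} A_i

— the manifold region the clone occupies. Expanded clones (≥ 5 cells) are
clustered on cosine distance between their w_c vectors (kNN k = 10, SNN
Jaccard weights, Louvain) into clonotype groups, which are annotated by the
ternary rule: a TH1-biased group's median clone has > 40% TH1 and < 20% TFH
member cells (TFH-biased symmetrically, otherwise mixed). Phenotype
co-occurrence within clones is tested against a clone-size-preserving
permutation null (labels shuffled over cells, clone partition fixed, 500
permutations, empirical two-sided p with the +1 correction).

Around the core: QC filters and two normalization dialects, mean-binned
dispersion HVG selection, a rank-sum DE stand-in with exact printed
thresholds, diffusion imputation (P^t·X) and diffusion maps/distances,
signature scoring with percentile binning (60th percentile / top 5%), a
nine-gene marker-PC classifier with MCC-maximizing threshold for purging
CD8 contaminants, and replicate-concordance metrics (z-scored centroid
correlations with automatic cluster matching, overlap coefficient, adjusted
Rand index). A negative-binomial generator with planted states, smooth
trajectories and archetype-driven clonotypes replaces the original
deposited datasets.

## Worked example

```r
library(clonofate)

sim <- simulate_clonal_cohort(n_per_state = 1000, n_clones = 30,
                              size_range = c(5, 20), seed = 1)
res <- run_fate_bias(sim$cm, sim$clones, n_perm = 500, seed = 1)
res$bias$group_archetype
res$null
```

On this cohort (3,000 cells, 90 clones: 30 per archetype with fate
probabilities (0.7, 0.1, 0.2), (0.1, 0.7, 0.2), (0.4, 0.35, 0.25)) the run
prints:

```
TH1_biased group (n=43): median fractions TH1=0.62 TFH=0.13 pTCM=0.17
TFH_biased group (n=38): median fractions TH1=0.15 TFH=0.68 pTCM=0.15
         combo observed expected deviation      p
1          TH1        2     0.05      1.95 0.0020
2          TFH        1     0.04      0.96 0.0339
3         pTCM        0     0.04     -0.04 1.0000
4      TH1+TFH        4     2.33      1.67 0.2480
5     TH1+pTCM        9     2.29      6.71 0.0020
6     TFH+pTCM        7     2.54      4.46 0.0140
7 TH1+TFH+pTCM       67    82.73    -15.73 0.0020
```

The TH1-biased group's median clone sits at 62% TH1 / 13% TFH — inside the
ternary corroboration rule — and single-fate and two-fate clone
combinations are over-represented relative to the size-preserving null
(fewer fully promiscuous clones than chance), i.e. the planted clonal fate
bias is detected.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulation → state clustering → fate bias → imputation stability →
CD8 purging → signatures & concordance), writing tables under `results/`.

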