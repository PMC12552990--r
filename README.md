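# c9methpred

Detection of pathogenic *C9orf72* repeat-expansion carriers from blood DNA
methylation arrays.

The GGGGCC hexanucleotide repeat expansion in the *C9orf72* promoter region
is the most frequent genetic cause of frontotemporal dementia and
amyotrophic lateral sclerosis. Expanded alleles are hypermethylated in
*cis*, and the signal survives into whole-blood EPIC-array data. This
package implements the full analysis chain that turns that observation into
a screening tool, and a synthetic cohort generator so the chain can be run,
tested, and benchmarked end to end without protected human data. It is
aimed at statistical geneticists and epigenetics groups who want either the
pipeline itself or a reference implementation of its components.

## What it computes

* **Differential methylation.** Per probe $j$, OLS on the M scale
  ($M = \log_2(\beta/(1-\beta))$):
  $M_{ij} = \alpha_j + \gamma_j\,\mathrm{carrier}_i + \mathbf{x}_i^\top\boldsymbol\beta_j + \epsilon_{ij}$
  with age, sex, five of six blood cell fractions, smoking score and batch
  in $\mathbf{x}_i$. Residual variances are shrunk toward a scaled
  inverse-chi-square prior fitted by moment matching on $\log s_j^2$
  (empirical-Bayes moderation, implemented in the package and cross-checked
  against limma in the tests); moderated t statistics get
  Benjamini–Hochberg adjustment and a genomic-inflation diagnostic
  $\lambda_{gc}$.
* **Permutation significance threshold.** Carrier labels are shuffled
  $B = 100$ times (carrier count preserved, covariates fixed), the full
  moderated analysis is re-run each time, and the smallest p-value seen
  across all permutations becomes the data-specific genome-wide threshold.
* **Locus classifier.** Restricted to the 23 CpG probes in *C9orf72* ± 1 kb,
  an L1-penalised logistic regression (10-fold cross-validated penalty,
  features standardised by training mean/SD) predicts carrier status;
  evaluation runs 100 repeated 70/30 stratified splits, reporting accuracy
  and type I/II error. Platform subsets (EPICv2/EPICv1/450K/27K →
  23/12/5/2 probes) quantify how shrinking array content degrades the
  classifier. Frozen models serialise to plain text and apply unchanged to
  independent cohorts.

## Worked example

A compact version of the whole chain (2,000 background probes and 20
permutations/splits instead of the 20,000/100 used by the analysis
scripts):

```r
library(c9methpred)

cfg <- implant_table1_profile(sim_config(n_background_probes = 2000, seed = 7))
coh <- generate_cohort(cfg)              # 277 samples, 27 carriers

res  <- run_dma(coh$dataset)
perm <- permutation_threshold(coh$dataset, B = 20, seed = 7)
sig  <- call_significant(res, perm$threshold)
print(res); print(perm)
sig[, c("probe_id", "coef", "t", "p", "adj_p", "direction")]

probes <- select_locus_probes(coh$annotation, "epicv2")
repeated_evaluation(coh$dataset, probes, n_iter = 20, root_seed = 7)
```

which prints:

```
dma_result: 2023 probes, 264 residual df, moderated (d0 = 3.98, s0^2 = 0.1255)
  lambda_gc = 1.048
permutation_result: 20 label permutations
  threshold (min p over permutations): 2.67e-05
  min p range: [2.67e-05, 0.00174]
    probe_id coef    t         p     adj_p direction
1 cg13533410 4.01 54.9 9.35e-148 1.89e-144     hyper
2 cg01589701 3.64 53.9 6.73e-146 6.81e-143     hyper
3 cg01589155 3.57 49.8 2.13e-137 1.44e-134     hyper
4 cg14363787 2.93 40.2 1.86e-115 9.41e-113     hyper
5 cg23074747 2.63 38.4 7.73e-111 3.13e-108     hyper
6 cg03854581 2.20 28.2  3.51e-82  1.18e-79     hyper
7 cg13533404 1.87 28.0  2.10e-81  6.08e-79     hyper
8 cg05151778 1.66 24.3  1.50e-69  3.79e-67     hyper
evaluation_result: 20 repeated splits
  accuracy mean 1.0000 (sd 0.0000)
  type1    mean 0.0000 (sd 0.0000)
  type2    mean 0.0000 (sd 0.0000)
```

Reading this: the genome-wide fit is well calibrated
($\lambda_{gc} \approx 1$), label noise alone never got below
$2.7\times10^{-5}$, and exactly the eight implanted locus CpGs clear that
threshold — all hypermethylated in carriers, in the implanted effect-size
order. The locus classifier then separates carriers essentially perfectly
on this synthetic cohort; on real cohorts the separation is cleaner at the
EPIC generation of arrays than at 450K/27K content, which
`platform_degradation()` quantifies.

## The analysis workflow

`analysis/` contains numbered drivers that run the study end to end at full
scale (20,000 background probes, 100 permutations, 100 repeated splits),
writing compact tables under `results/`:

1. `01_simulate.R` — generate the discovery cohort, export locus matrix,
   covariates, ground truth.
2. `02_qc_filter.R` — call-rate and probe-flag accounting
   (440 → 434 → 277 samples).
3. `03_differential_methylation.R` — genome-wide moderated fit, top table,
   $\lambda_{gc}$.
4. `04_permutation_threshold.R` — 100-permutation threshold, significant
   probes.
5. `05_locus_classifier.R` — PCA, single-split LASSO, frozen model.
6. `06_platform_comparison.R` — per-platform repeated evaluation + Welch
   comparisons.
7. `07_independent_validation.R` — frozen model applied to a 2,458-sample
   cohort with 4 hidden carriers.

Run them in order from the repository root, e.g.
`Rscript analysis/03_differential_methylation.R`.

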