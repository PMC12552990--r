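---
title: "Methods: detecting C9orf72 repeat-expansion carriers from blood DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting C9orf72 repeat-expansion carriers from blood DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The GGGGCC hexanucleotide repeat expansion in the *C9orf72* promoter is the
most common genetic cause of frontotemporal dementia and amyotrophic lateral
sclerosis. Expanded alleles are hypermethylated in *cis*: CpG sites in and
around the gene carry higher methylation in expansion carriers, and the
signal is detectable in whole-blood array data. `c9methpred` implements the
resulting analysis chain — genome-wide differential methylation to locate the
signal, a permutation-calibrated significance threshold, and a
locus-restricted sparse logistic classifier that screens cohorts for
carriers — together with a synthetic cohort generator that reproduces the
statistical structure the chain assumes, so every stage can be exercised and
tested without access to protected human data.

## Data model and scale

Methylation is measured per CpG probe either as a beta-value (methylated
signal fraction, in $[0,1]$) or as an M-value, the log2 odds
$M = \log_2\!\big(\beta/(1-\beta)\big)$. All modelling here happens on the M
scale, whose variance is far less mean-dependent than the beta scale;
`beta_to_m()` / `m_to_beta()` convert between the two. Betas are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the log
ratio so fully (un)methylated probes stay finite; the two functions are exact
inverses away from the clip boundary.

A `meth_dataset` couples the samples × probes M-value matrix with per-sample
covariates — age (years), sex (0/1), six reference-based blood cell fractions
(CD8T, CD4T, NK, B, monocytes, neutrophils; proportions summing to one),
a continuous smoking score, and an experimental batch label — plus a
tri-state carrier annotation (`carrier` / `non_carrier` / `unknown`).
Matrices, covariate tables and probe manifests travel as delimited text with
an explicit orientation flag; missing values are `NA`, never zero.

Quality control is flag-based: the probe manifest carries `qc_flags`
(`low_detection`, `sex_chromosome`, `snp_overlap`, `cross_reactive`,
`manufacturer_flagged`) and `filter_probes()` removes any probe whose flags
intersect the requested drop set, reporting counts per category and per
chromosome. Raw intensity processing is out of scope, so the detection-p
decision is represented by the pre-computed flag rather than a cutoff applied
here. `filter_samples()` drops samples whose missing fraction exceeds a call
rate threshold (default 5%). Probes with any remaining missing value are
removed before modelling (`drop_incomplete_probes()`): per-probe least
squares needs complete columns, and imputation is deliberately not offered.

## Per-probe differential methylation

For each probe $j$, the M-values are regressed on carrier status with the
full covariate set:

$$ M_{ij} = \alpha_j + \gamma_j \, \text{carrier}_i + \mathbf{x}_i^\top
\boldsymbol\beta_j + \epsilon_{ij} $$

where $\mathbf{x}_i$ stacks age, sex, five of the six cell fractions,
smoking score, and batch dummies. Neutrophils — the dominant fraction — are
dropped because the six fractions sum to one and would make the design
singular; batch uses first-level-reference dummy coding. The fit is a single
QR decomposition shared by all probes, so a genome-wide pass over
20,000 probes takes about a second. Rank-deficient designs (for example a
batch perfectly aligned with carrier status) are refused with the offending
columns named; probes with zero residual variance are flagged and excluded
from p-value ranking rather than given $p = 1$.

### Variance moderation

With only 27 carriers, per-probe variance estimates are noisy and the
smallest ones produce spuriously large t statistics. The per-probe variances
$s_j^2$ (each on $d$ residual degrees of freedom) are therefore shrunk
toward a global prior before testing. We fit a scaled inverse-chi-square
prior with $d_0$ degrees of freedom and scale $s_0^2$ by matching the first
two moments of $\log s_j^2$: with
$e_j = \log s_j^2 - \psi(d/2) + \log(d/2)$,

$$ \psi'(d_0/2) = \operatorname{var}(e) - \psi'(d/2), \qquad
   \log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2), $$

solving the trigamma equation by Newton iteration. The posterior variance
$\tilde s_j^2 = (d_0 s_0^2 + d\, s_j^2)/(d_0 + d)$ yields the moderated
statistic $\tilde t_j = \hat\gamma_j / (\tilde s_j c_j)$ on $d_0 + d$
degrees of freedom, where $c_j$ is the unscaled standard-deviation factor
from $(X^\top X)^{-1}$. When the observed variances show no spread beyond
chi-square sampling noise the prior degrees of freedom are infinite and
every probe uses the pooled variance (with a normal reference). The test
suite cross-checks $d_0$, $s_0^2$, the moderated t and p against an
independent empirical-Bayes implementation.

Multiple testing uses Benjamini–Hochberg step-up adjustment (the adjusted
p column of the result table), and `genomic_inflation()` reports
$\lambda_{gc}$ — the median of the 1-df chi-square quantiles of the p-values
over the null median $\approx 0.4549$, rounded to three decimals — as the
standard check that covariate adjustment has removed systematic inflation.
Moderated p-values feed every downstream threshold.

## Permutation significance threshold

A fixed epigenome-wide threshold ($9\times10^{-8}$) does not account for the
severe 27:250 class imbalance, so the package also calibrates a
data-specific threshold: carrier labels are shuffled across samples
(preserving the carrier count — a permutation test conditions on the
observed margin), covariates stay attached to their samples so the null
retains the covariate structure, the full moderated analysis is re-run per
permutation, and the smallest carrier p-value of each of the $B = 100$
re-analyses is recorded. The threshold is the minimum over all permutations
— the best result label noise alone ever achieved — and observed probes are
called significant only when strictly more significant than it. A
permutation that happens to reproduce the original labels is kept and
counted (resampling it would bias the null); a rank-deficient permuted
design is redrawn and reported. Permutation $b$ is seeded `seed + b`, making
the result deterministic and the threshold non-increasing as permutations
are added.

## The locus classifier

Prediction is restricted to the 23 probes inside the *C9orf72* gene and its
1-kb flanks, as carried by the packaged manifest (`in_region`). The
manifest's platform flags encode how array content shrinks backwards in
time: 23 probes on EPICv2, 12 on EPICv1, 5 on Methyl450K, 2 on Methyl27K.
For a pre-flight look, `locus_pca()` gives the first two column-centred
principal components of the locus submatrix (sign fixed so the first
probe's loading is non-negative), in which carriers separate cleanly when
the hypermethylation signal is present.

The classifier is an L1-penalised logistic regression: features are
standardised by training mean and SD, the penalty path is searched by
10-fold cross-validation minimising binomial deviance, and the final model
is refit on the full training set at the deviance-minimising penalty
(`lambda.min`; the 1-SE rule trades accuracy for sparsity and is not used —
the choice is recorded in the model metadata). Folds and train/test splits
are stratified by carrier status: with 27 carriers among 277 samples an
unstratified 30% test set can contain no carriers at all, leaving the
false-negative rate undefined, so stratification is the default and an
unstratified mode exists for sensitivity checks. The per-class training
count is `round(0.7 * n_class)` (19 carriers + 175 non-carriers = 194 of
277). Predicted probability is
$\operatorname{logit}^{-1}(b_0 + \sum_j b_j z_j)$ on the standardised
M-values; a sample is called a carrier above 0.5. Frozen models serialise
to plain text (intercept, penalty, per-probe centre/scale/coefficient), so
a model trained once can be applied unchanged to any later cohort;
prediction refuses datasets missing a model probe rather than imputing.

`repeated_evaluation()` wraps the split–train–predict cycle over (by
default) 100 iterations with per-iteration seeds `root_seed + i`, reporting
accuracy, type I error FP/(FP+TN) and type II error FN/(FN+TP) per
iteration with exact summary means. `platform_degradation()` runs the same
evaluation on each platform's probe subset — sharing split seeds across
platforms by default so the comparison is paired — and compares metric
distributions between platforms with a two-sided Welch t test (a Wilcoxon
option is available; identical degenerate distributions are reported as
statistic 0, p 1 rather than an error).

## The synthetic cohort generator

`sim_config()` + `generate_cohort()` produce an EPIC-style cohort with the
structure the analysis assumes; everything derives from one integer seed and
regenerating with the same configuration is bit-identical.

* **Cohort**: 277 samples, 27 carriers by default. Age ~ N(63, 8) truncated
  to [30, 95], sex ~ Bernoulli(0.4), cell fractions from a
  neutrophil-dominant Dirichlet (concentration 60, mean neutrophil share
  0.56; sums to one exactly), smoking score ~ N(0, 1), batches uniform over
  4 levels.
* **Probes**: the 23-probe locus manifest plus (default) 20,000 genome-wide
  background probes. Baseline means follow the canonical island
  hypomethylation gradient — mean beta 0.15 in islands, 0.35 shores, 0.55
  shelves, 0.75 open sea — converted to M with probe-level jitter (SD 0.5).
* **Effects**: the eight locus CpGs known to be hypermethylated in carriers
  (`implant_table1_profile()`) receive carrier-specific M shifts from +4.0
  down to +1.5 in rank order. These magnitudes are a calibration choice,
  not a measured quantity: published fold-change columns are not
  interpretable as M-value differences, and strip-plot-style separations of
  several M units are what cleanly separated carrier clouds look like. At
  27 versus 250 the weakest implanted probe has an expected |t| around 13,
  so recovery is a designed property of the default conditions, not luck.
* **Noise**: homoscedastic per probe on the M scale. Locus probes use the
  fixed `noise_sd_m = 0.35`; background probes draw their SD from a
  lognormal with median 0.4 and sdlog 0.4, giving the variance
  heterogeneity that moderation exists to shrink.
* **Confounding**: a random 10% of probes get covariate slopes (age SD
  0.005/yr, sex 0.15, smoking 0.10, one random cell fraction 0.8, all M
  units) and every probe gets per-batch offsets (SD 0.15), so the covariate
  adjustment is load-bearing rather than decorative.
* **Accounting**: optional call-rate failures (samples forced above the 5%
  missingness cut) and unknown-label samples (drawn from non-carriers,
  emulating subjects without repeat-length data) reproduce the intake
  arithmetic 440 − 6 − 157 = 277.
* `generate_independent_cohort()` hides the labels: the dataset reports
  every sample as `unknown` and truth lives only in the returned ground
  truth, so frozen-model screening is tested end to end.

What the generator does **not** emulate: probe type I/II chemistry and
normalisation artefacts, spatial correlation between neighbouring locus
CpGs (implanted effects are independent across probes), somatic repeat-length
heterogeneity, or ancestry structure. Synthetic separations are consequently
cleaner than real ones — repeated-split accuracy here sits at or near 100%,
comfortably above the high-90s reported for real blood cohorts — so passing
benchmarks demonstrate that the machinery recovers what was implanted under
realistic covariate/batch noise, not that a real cohort would achieve the
same figures.

## Numerical choices and edge cases

* Beta clipping $\varepsilon = 10^{-6}$; p-values are floored at the
  smallest positive double so they stay in $(0, 1]$.
* Zero-variance probes: coefficient 0, excluded from ranking, permutation
  nulls and significance calls.
* Trigamma inverse: Newton iteration to relative tolerance $10^{-10}$.
* `lambda_gc` of an all-ones p-vector is 0 with a warning (degenerate, not
  an error); fewer than 100 p-values is an error.
* Welch comparisons of two identical constant metric vectors return
  statistic 0, p 1.
* Fitted probabilities are invariant (to $10^{-6}$) under affine rescaling
  or duplication of input features, since standardisation absorbs both.
* Problem sizes used by the test suite and the analysis scripts: 20,000
  background probes, 100 permutations, 100 repeated splits for the headline
  runs; smaller cohorts (60–300 samples, 100–2,000 probes) for unit and
  property checks. These sizes keep a full run in the low minutes on one
  core while leaving every statistical property measurable.

## Known limitations

Covariates are taken as given (cell fractions and smoking scores are
upstream estimates in practice); the pipeline starts from a cleaned M-value
matrix, not IDATs; the permutation threshold re-uses fixed covariates per
permutation (re-estimating them per shuffle is not modelled); and the
classifier is a screening tool — in any real deployment, predicted carriers
require orthogonal confirmation (repeat-primed PCR) before any clinical
interpretation.
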