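---
title: "Comparing genomic selection models for nitrogen use efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing genomic selection models for nitrogen use efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsnue)
```

## The problem

Genomic selection (GS) predicts the additive genetic merit of a candidate
genotype — its genomic estimated breeding value (GEBV) — from genome-wide
SNP markers, using a model trained on individuals that are both genotyped
and phenotyped. For a trait as expensive to phenotype as nitrogen use
efficiency (NUE = grain yield per unit nitrogen supplied, measured here
under a low-N and a high-N regime), the practical question is which of
the many available GS models to trust, and how much genetic gain
selecting on its GEBVs can be expected to deliver.

`gsnue` implements nine predictors spanning the main inference families —
rrBLUP and gBLUP (frequentist mixed models), LASSO and Bayesian ridge
(penalized/Bayesian whole-genome regression), RKHS kernel regression and
ε-insensitive support vector regression (kernel methods), and gradient
boosting, bagging and stacking (ensembles) — together with the
surrounding evaluation machinery: marker quality control, relationship
and kernel matrices, REML variance components and SNP heritability,
nested cross-validation, a bias–variance decomposition, a pairwise
adaptive-standard-error comparison, and a selection-gain calculation.

## The synthetic study population

The field dataset the design emulates (221 bread wheat genotypes, a 150K
SNP chip reduced to 22,489 polymorphic markers after quality control,
NUE under two N levels) is not publicly deposited, so the package treats
the *population model* as part of the software: every analysis stage is
exercised end-to-end on simulated data whose generating process is fully
known.

`simulate_genotypes()` draws biallelic dosages as follows. Ancestral
alternate-allele frequencies are uniform on `[maf_low, maf_high]`
(default 0.05–0.5). Three subpopulation clusters (the structure analysis
of the emulated panel found K = 3 optimal) drift from the ancestral
frequencies under a Balding–Nichols model with an Fst-like parameter
(default 0.1, enough for the leading two principal components to
separate the clusters). Within each subpopulation a pool of founder
haplotypes (default 100 — a broad, diversity-panel-like base rather than
a family cross) is simulated with a latent Gaussian factor shared by the
markers of each LD block (block length default 10, within-block loading
0.7), so adjacent markers are positively correlated while marginal
frequencies are preserved; each gamete then copies one founder per block
and flips alleles at a small mutation rate. Missing calls are injected
completely at random (default 2%).

`simulate_phenotypes()` lays an additive architecture on top: `n_qtl`
causal markers (default 200) receive effects drawn from a bivariate
normal across the two N environments with correlation 0.8 (a
genotype-by-nitrogen interaction of plausible strength), genetic values
are scaled to genetic variances of 30 (LN) and 15 (HN) squared NUE
units, and residual noise is scaled so that the *population-level*
variance ratio equals the target heritability exactly:
σₑ² = σₐ²(1 − h²)/h². Default targets are h² = 0.45 (LN) and 0.60 (HN),
inside the 0.28–0.71 range such panels report. NUE is generated first
(means 45 at LN with Ns = 10 g N/m², 25 at HN with Ns = 22) and grain
yield and total plant N are derived so that NUE = GY/Ns holds exactly.

What the generator does *not* emulate: recombination maps and coalescent
LD decay, dominance and epistasis, selection history, spatial field
trends, genotype-by-year effects, and informative missingness. Passing
tests therefore demonstrate correctness of the estimators under a known
additive model with realistic structure — not robustness to every
pathology of real field data.

## Quality control and kinship

`apply_qc()` removes markers with folded MAF ≤ 0.05 (inclusive
boundary), markers failing a one-degree-of-freedom Hardy–Weinberg
chi-square at α = 1e-4, and markers called in fewer than 95% of
genotypes, in that order of precedence so the report counts are
exclusive. The HWE and call-rate defaults are conventional choices (the
emulated protocol states only that both screens were applied) and are
exposed as arguments. Remaining missing dosages are mean-imputed per
marker — the simplest completion that keeps the downstream linear
algebra exact; markers are then coded (−1, 0, 1) as dosage − 1.

`build_grm()` is the allele-frequency-scaled cross-product
G = W W′ / (2 Σ pₖ(1 − pₖ)) with W column-centered at 2pₖ — the standard
construction whose diagonal averages about 1 under Hardy–Weinberg
proportions. `build_gaussian_kernel()` gives
K = exp(−d²/(2θ²)) on Euclidean distances between centered coded rows,
with the median off-diagonal distance as the default bandwidth (no
bandwidth is prescribed by the design; the median heuristic is the
standard scale-free choice). Kernel and ensemble models consume this
kernel or the coded markers directly; the GRM serves the BLUP family.

## The nine predictors

* **rrBLUP** solves the intercept-augmented mixed-model equations with
  ridge shrinkage λ = σₑ²/σ_g² on marker effects. The system is solved
  in its n × n dual form (with the dual block rescaled by its mean
  diagonal so the bordered system stays well-conditioned even under
  extreme shrinkage), so 2,000-marker panels cost one small solve.
* **gBLUP** is the individual-level dual: u ~ N(0, G σᵤ²) with the GRM,
  fitted with a GLS intercept. With G = XX′/c and the mapped ratio the
  two give identical GEBVs — the package's central internal consistency
  check.
* **LASSO** minimizes (1/2n)‖y − μ − Xβ‖² + λ‖β‖₁ by cyclic coordinate
  descent with soft-thresholding, an active working set and vectorized
  KKT screening; convergence uses the glmnet criterion (largest weighted
  squared coefficient move relative to the phenotypic variance, 1e-7).
  The penalty path (15 log-spaced values down to 5% of λ_max) is scored
  by inner cross-validation; path fits stop once the active set
  saturates at the training-set size, where the CV curve is already
  rising.
* **Bayesian ridge** places a common Gaussian prior on all marker
  effects with scaled-inverse-chi-square priors on both variances. The
  Gibbs sampler works in the eigenbasis of the centered marker matrix:
  rotated coordinates are conditionally independent, the null-space
  squared norm is a chi-square draw, and each sweep is O(n), so long
  chains are cheap. Effects are summarized by posterior means and
  posterior sign probabilities (a normal approximation from the
  posterior mean and variance) — the package's per-marker summary of the
  "all effects zero" null hypothesis.
* **RKHS** is kernel ridge regression; its λ comes from REML on the
  kernel (the RKHS/gBLUP duality), or can be supplied.
* **SVR** solves the ε-insensitive dual by pairwise analytic coordinate
  ascent under the box and equality constraints. When no free support
  vector pins the bias (everything inside the tube), the bias is the
  midrange of y — a deterministic tie rule. Defaults scale with the
  trait: ε = 0.1 sd(y), C = sd(y).
* **Boosting** is stage-wise squared-loss gradient boosting from F₀ = 0
  with depth-limited regression trees; **bagging** aggregates trees over
  bootstrap resamples and reports out-of-bag error. The weak learner is
  a CART-style tree specialised to marker columns: because coded dosages
  take three levels, the exhaustive variance-reduction split search
  reduces to two crossprod calls per node over all markers, making a
  tree fit a few milliseconds on thousands of markers with no feature
  subsampling and fully deterministic splits (verified split-for-split
  against an rpart stump in the tests).
* **Stacking** combines the other models by meta-learning: non-negative
  least squares (Lawson–Hanson active set, free intercept) of the
  phenotype on the base models' out-of-fold predictions, so weights are
  learned without leakage and read as an interpretable mixture. An
  ε-insensitive variant iteratively ignores observations inside the
  tube, mirroring a stacking loss that charges nothing below ε. The
  out-of-fold base fits reuse the hyper-parameters already tuned on the
  training split (REML ratios, the CV-chosen LASSO penalty) rather than
  re-tuning inside each fold — three cheap refits per base instead of
  three tuning runs, which is what keeps all-model stacking tractable in
  nested cross-validation on one core.

## Variance components and heritability

`estimate_variance_components()` fits y = 1μ + g + e with
g ~ N(0, K σₐ²) by REML: one eigendecomposition of K turns the
restricted likelihood into a 1-D profile over λ = σₑ²/σₐ², maximized on
a 121-point log grid over λ ∈ [1e-6, 1e6] and refined by golden-section
search. SNP heritability is h² = σₐ²/(σₐ² + σₑ²) = 1/(1 + λ). An
essentially-identity kinship triggers an identifiability warning (the
two components are then confounded) and returns the boundary estimate.
At the study scale (a few hundred genotypes, LD-heavy panels) single-run
h² estimates carry a sampling SD near 0.1; averages over simulation
replicates are essentially unbiased.

Models that do not estimate REML components (LASSO, SVR, the ensembles)
are summarized by empirical components — the variance of training GEBVs
against the variance of training residuals. This is a training-fit-based
summary: for flexible learners it can exceed the REML heritability, and
the report columns should be read with that in mind.

## Evaluation design

`cv_plan()`/`run_nested_cv()` implement the nested reading of a
"10-fold training, 5-fold testing" cross-validation: outer 5-fold
partitions supply held-out test genotypes; inner 10-fold splits of each
training set tune hyper-parameters. The literal alternative — two
independent K-fold CVs, one per phase — is available behind
`mode = "independent"`. Held-out genotypes never contribute their
phenotypes to the folds that predict them; relationship and kernel
matrices are built once from genotypes only (standard GS practice, as
candidate genotypes are known at prediction time). Per model and N
level the report mirrors the usual genetic-parameter table: SNP
heritability, genetic and error variance (per-fold averages), train- and
test-phase GEBV means with a percentile-bootstrap interval, accuracy
r(y, GEBV), a Welch (unequal-variance) t-test of train-vs-test GEBV
means, and the learning-rate summary. The decaying schedule
α_j = 100·α₀/(100 + j) reaches 0.01 after 9,900 epochs with α₀ = 1;
`learning_rate_schedule()` exposes the full trace and boosting can run
under it.

## Bias–variance decomposition

`knn_bias_variance()` sweeps a k-nearest-neighbour reference family over
model complexity (the neighbour count). One superpopulation is simulated
so the genotype-to-trait function is fixed; a held-out test set keeps
known true genetic values; each of B resamples draws a fresh training
set from the pool with fresh phenotype noise. Per complexity:
bias² = mean over test points of (mean prediction − truth)², variance =
mean across-resample prediction variance, expected loss = mean squared
error against noisy test responses, and the irreducible error is the
generator's true σₑ². The additive identity
E[loss] = bias² + variance + σₑ² holds within Monte-Carlo error, and the
sweep shows the classical tradeoff — variance falling and bias rising
with k as predictions collapse toward the population mean. On fixed
(non-synthetic) data the routine bootstraps training rows, uses held-out
phenotypes as targets, and reports the residual loss floor as the noise
estimate. `estimate_irreducible_error()` also supports replicate-based
estimation (within-genotype variance of repeated records).

## Pairwise model comparison

The "adaptive standard error of prediction" stage compares fitted models
on a shared 75/25 test partition. Each model's marker-effect profile
(native for linear/Bayesian models; a light ridge back-projection of
GEBVs onto the coded markers for kernel and ensemble fits) is
standardized and screened against the N(0, 1) null:
`null_effect_resampling()` resamples the standardized pool 2,000 times
with replacement, two-sided normal p-values are adjusted by
Benjamini–Hochberg at FDR 0.05. A pair in which neither model carries
any effect signal beyond the null reports a raw adaptive SE of zero —
indistinguishable from noise. Otherwise the raw value is the bootstrap
standard error of the mean paired difference in squared prediction
errors. The matrix (including the zero diagonal) is min-max normalized
to [−0.2, 1]. `declare_differences()` turns the pairwise
normal-approximation p-values into BH-controlled declarations; under an
exchangeable null the declaration rate stays at or below the nominal
level (the screen makes the procedure conservative), which the
acceptance suite verifies over 200 simulated repetitions.

## Selection gain

`gain_report()` splits the population 75/25 (floor rounding, seeded
shuffle), fits the chosen model (default the stack) per N level, and
measures test accuracy r. The model-power term is read off Henderson's
mixed-model coefficient matrix
C = [[X′X, X′Z], [Z′X, Z′Z + G⁻¹σₑ²/σᵤ²]] as β = logdet(C)/dim(C) — an
information-content summary that grows with added genotypes and design
density; X encodes the subpopulation structure, Z the genotype design,
and G⁻¹ comes from `regularized_inverse()` with logged jitter
escalation. Expected gain and genetic gain are the literal products
R = i·r·y·β and ΔG = i·β·σₑ (a conventional per-year variant divides R
by y behind a flag), with the selection intensity i derived from the
selected fraction by the normal truncation relation. Relative efficiency
is RE = r/R², reported per N level and as a percentage. The top-k
genotypes per level (ties broken by id) are listed with a per-genotype
RE% — each genotype's share of the top-set GEBV total scaled by the
population RE, a display convention — along with the cross-level overlap
set, whose minor- and major-allele contents are contrasted against the
whole population by Welch tests. If the chosen model degenerates to a
constant predictor on a split (possible for a non-negative stack with no
useful base), accuracy is set to 0 with a warning and RE is reported
missing rather than aborting the report.

## Numerical choices and degenerate inputs

* Mixed-model solves use a bordered augmented system with the dual block
  rescaled by its mean diagonal; singular systems escalate a diagonal
  jitter before failing.
* `regularized_inverse()` starts at jitter 1e-6 (or 0) and escalates
  tenfold until the Cholesky succeeds, recording the escalations.
* REML profiles λ on a log grid bounded at [1e-6, 1e6]; boundary optima
  are flagged.
* KNN distance ties break to the lowest training index; SVR's
  non-unique bias breaks to the midrange of y; top-list GEBV ties break
  to the genotype id — every tie rule is deterministic.
* All stochastic stages draw their seeds as fixed substreams of one
  global seed, so a pipeline run is bitwise reproducible (the manifest
  md5 checksums are identical across runs with the same config).

## Problem sizes

The test-suite and acceptance runs use panels scaled for a single core:
populations of 50–400 genotypes and 80–2,000 markers, 200 bias–variance
resamples, 2,000 effect resamples, 30 replicate simulations for
heritability recovery, and a full nine-model pipeline at the study shape
(221 genotypes × 2,000 markers, completing in a few minutes). The same
code runs unchanged at chip scale; only the matrices grow.

## Known limitations

Marker effects are additive only; BayesA/B/Cπ-style heavy-tailed priors
are out of scope (the Bayesian model is a ridge). The generator's LD is
blockwise rather than distance-decaying, and QC operates per marker
(no sample-level QC, matching the emulated protocol). The empirical
variance components of non-REML models are descriptive, not estimates of
the same estimand as REML. The adaptive-SE comparison is one documented
operationalization of a loosely specified construct; its FDR screen is
deliberately conservative.
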