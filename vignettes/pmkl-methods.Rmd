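---
title: "Methods: probabilistic multiple-kernel prognosis and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic multiple-kernel prognosis and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters that matter, what the
synthetic-cohort generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## 1. The prognostic problem

Mild cognitive impairment (MCI) is a transitional state between normal
cognitive aging and dementia. A clinically useful prognostic model must
say, for an individual MCI patient at baseline, how likely progression to
AD-type dementia is within a fixed horizon (here: 36 months, on a
follow-up visit grid of 6/12/18/24/36 months) — and how confident that
statement is. The package therefore centres on a classifier that outputs
posterior class probabilities rather than hard labels, and on analyses
that exploit them: calibration, reject-option classification, and
Bayes-rule translation into post-test probabilities.

Baseline data come from four heterogeneous sources — clinical risk factors
(CRF), cognitive and functional assessment scores (CAM), MRI morphometric
measures (MRI) and plasma proteomic analytes (PPM) — of very different
dimensionality and signal content. Multiple kernel learning is the natural
formalism: one kernel per source, combined with learned nonnegative
weights, so the model itself reports how much each source contributes.

## 2. The classifier

Subjects are represented by kernel similarity to the training subjects.
Let `K_m` be the Gram matrix of kernel `m` (linear, polynomial or
Gaussian, on a feature subset). The composite representation is
`K = Σ_m β_m K_m` with `β` on the probability simplex, and each subject's
row is augmented with a constant bias element. Class membership follows
the multinomial probit likelihood

$$P(Y_n = i \mid W, k_n) \;=\; \mathbb{E}_{u \sim N(0,1)}
\Big\{ \prod_{j \ne i} \Phi\big(u + (w_i - w_j)\,k_n\big) \Big\},$$

with `W` the classes-by-(n+1) matrix of regression coefficients — the
weights with which training subjects vote for each outcome. For two
classes this reduces to `Φ(a/√2)` at margin `a = (w_1 − w_2)·k_n`, which
the test suite uses as a closed-form oracle for the Monte-Carlo estimator.

**Inference.** The posterior over `W` is sampled by Gibbs with the
classical auxiliary-variable probit augmentation: each subject carries one
latent Gaussian score per class, truncated so the observed class attains
the maximum; `W` then has conjugate Gaussian updates under a
`N(0, τ⁻¹I)` prior with `τ ~ Gamma(0.01, 0.01)`. A variational scheme
would satisfy the same probabilistic contract; the sampler was chosen as
the reference because it is exact in the limit and simple to verify at
desk scale. The per-sweep cost is dominated by an eigendecomposition of
`AᵀA` (A the bias-augmented composite kernel), which is cached and only
refreshed when `β` moves.

**Kernel weights.** `β` is updated by Metropolis-within-Gibbs every
`beta_every` sweeps (default 10): a Dirichlet proposal centred on the
current weights (concentration `beta_proposal_conc`, default 100), a flat
`Dirichlet(1)` prior, and the latent-score Gaussian likelihood in the
acceptance ratio. On synthetic cohorts with signal confined to one source
the posterior mean weight concentrates on that source's kernel (tested
over 10 seeds).

**Prediction.** The probit expectation is realized with `n_mc_probit`
standard-normal draws (default 1000) shared across classes and subjects
(common random numbers), and the probability vector is renormalized. The
binary decision rule calls "progressor" when that probability exceeds the
threshold (default 0.5); a probability exactly at the threshold is called
non-progressor and flagged as a tie — the conservative choice, avoiding a
"progressor" call at zero evidence.

**Defaults and units.** Chain length 2000 with 500 burn-in; posterior
means are reported. All features are standardized (training statistics
only) before kernels are computed; Gaussian bandwidths default to the
median heuristic (median pairwise distance among training rows, zero
distances excluded), and each Gram matrix is trace-normalized
(`K ← K·n/trace(K)`) so that `β` is comparable across sources of different
dimensionality. The normalization convention and the per-source grouping
of the multiple-kernel presets (one kernel per source with at least one
selected feature, plus one global kernel for the 5-kernel Gaussian preset)
are this package's documented choices; polynomial kernels default to
degree 2, offset 1.

## 3. Feature selection

The filter stage ranks features greedily under the joint mutual
information criterion: the first feature maximizes `I(X;Y)`; each later
candidate `k` maximizes `Σ_{j∈S} I((X_k, X_j); Y)` over the selected set
`S`. The pairwise joint terms reward complementarity (an XOR partner
scores `ln 2` where each marginal scores 0) and penalize redundancy (an
exact copy adds nothing). Mutual information uses plug-in estimates on
discretized features — default equal-frequency, 10 bins, robust to the
skewed marginals typical of proteomic analytes; the bin count and strategy
are configuration, not a claim about any particular upstream toolchain.
Ties break to the lowest feature index so rankings are reproducible, and
rankings are equivariant under subject permutation.

The wrapper stage — choosing how many ranked features to keep — lives in
the evaluation module's inner cross-validation loop: every candidate count
in `feature_grid` (default 1–50) is scored by mean inner-validation
balanced accuracy, and the smallest count attaining the maximum wins
(parsimony tie-break).

Features heavily right-skewed on the training rows (sample skewness > 2,
nonnegative values) are passed through `log1p` before z-scoring, since
analyte concentrations are classically log-normal; both behaviours are
configurable, and the exact transformation list applied upstream of any
particular dataset is a preprocessing concern outside this package.

## 4. Nested cross-validation and the model zoo

The evaluation design is a nested stratified k-fold cross-validation
(default 10×10). In each outer fold the held-out test set is untouched
while the development set is standardized, ranked, and inner-cross-
validated to pick `D_optimal`; the final model is refit on the whole
development set and evaluated once on the test fold. `D_optimal` is
selected per outer fold (and every value recorded), since the inner loop
operates inside each development set. Fold assignment keeps each class
within one subject of its proportional share, and all randomness flows
through explicit seeds — the whole experiment is bit-reproducible, and a
shared fold assignment across model specifications makes the per-fold
estimates paired for comparisons.

Inner-loop fits may use a shortened chain (default 300 sweeps) so the
wrapper grid stays tractable; the final fit in every outer fold always
uses the full settings. The reduced-scale experiments in the test suite
(k = 5, r = 2, n = 200, 60 features) were sized so that the complete suite
runs comfortably on a single CPU; they are stated as the package's own
problem sizes.

**Metrics.** Balanced accuracy `(Sn+Sp)/2` is the primary measure; AUC is
the Mann–Whitney probability with half credit for ties; calibration bins
pooled out-of-fold predictions into ten equal-width probability
sub-intervals and summarizes agreement between mean predicted probability
and observed event rate per bin with Lin's concordance correlation
coefficient (population moments). Pooling across repetitions before
binning is this package's choice; per-repetition CCCs are also recorded
for dispersion. When fewer than ten sub-intervals are occupied the CCC is
flagged unavailable rather than computed on a degenerate curve.

**Model comparison.** Performance differences over the k·r paired folds
are tested with the overlap-corrected repeated-CV t-test:
`t = mean(d) / sqrt((1/(kr) + ρ)·var(d))` with `ρ = (1/k)/(1 − 1/k)` (the
test/train size ratio), referred to a t distribution with `r` degrees of
freedom — the calibration appropriate for 10×10 experiments, rather than
the naive `kr − 1`. Calibration (CCC) differences, of which only one value
per repetition exists, use an ordinary paired t-test across repetitions.

**Type-I calibration of the corrected test.** The test suite verifies
type-I control with a null in which two single-source models are compared
on cohorts whose two sources carry effect sizes drawn exchangeably per
replication (`d ~ N(1, 0.35)` independently per source): marginally
neither model is better, yet each realized cohort favours one of them —
the across-dataset variability of relative performance that the
correction is designed to absorb. A null with literally identical models
is uninformative here: the paired differences are then exactly zero or
pure inference noise, under which the corrected test is vacuously
conservative (its assumed fold-difference correlation `ρ/(1+ρ)` far
exceeds the realized one) and the rejection rate is indistinguishable
from zero. The exchangeable-effects design is the standard construction
for evaluating corrected resampled t-tests.

## 5. Risk analyses

Predictive confidence is the gap between the two (largest) class
probabilities; confidence 0.4 corresponds to binary probabilities
(0.70, 0.30). The reject-option curve retains, at each threshold, the
subjects whose confidence meets it, and reports coverage plus metrics on
the retained set; coverage is non-increasing by construction and, on
calibrated predictions, retained-set balanced accuracy is non-decreasing
in the threshold in expectation (verified over 20 seeds at n = 2000).

Subgroup-stratified accuracy partitions the cohort by a covariate (age
band, sex, education, APOE ε4 carriage, AD-medication use, CVD-risk
count, depression history) or, for progressors, by time-to-progression
bins {0–6, 6–12, 12–18, 18–24, 24–36} months with a derived coarse split
at 18 months. Confidence intervals are taken across CV repetitions (the
available replication axis); strata smaller than 10 subjects are reported
but flagged unstable. Pooling all strata of a partition reproduces the
overall confusion counts exactly.

Post-test probabilities apply Bayes' rule to a pre-test prior π and the
model's operating point: positive `sn·π / (sn·π + (1−sp)(1−π))`, negative
`(1−sn)·π / ((1−sn)·π + sp(1−π))`; both are monotone in the prior and
bracket it whenever `sn + sp > 1`. The risk–time association among
progressors is a Spearman rank correlation with average-rank ties (ties
are the norm on a five-point visit grid) and a two-sided p-value from the
t approximation. Group comparisons at baseline use a pooled-variance
two-sample t-test for continuous variables (Welch available) and an
uncorrected Pearson chi-square on the 2×2 table for binary ones, with
degenerate inputs flagged rather than tested.

## 6. The synthetic cohort generator

The generator exists so that every downstream stage has a testable ground
truth; it emulates the *structure* of a two-group MCI cohort, not any real
dataset. Defaults: 120 non-progressors vs 139 progressors; feature
sources of dimension CRF 16 / CAM 170 / MRI 452 / PPM 149; a small planted
set of informative features with standardized mean shifts `d`; one-factor
equicorrelation ρ = 0.3 within each source (the simplest structure that
exposes the redundancy/complementarity trade-offs JMI must navigate); an
APOE-ε4-like binary covariate with prevalences 41.7% / 66.2% injected both
as a feature and as a stratum; progression times on the visit grid with
probabilities (0.10, 0.25, 0.25, 0.20, 0.20), giving median 18 months; and
an optional Gaussian-copula coupling that makes higher latent risk
stochastically earlier, to exercise the risk–time analysis. The latent
risk score is the standardized mean of a subject's informative features.

What it does **not** emulate: empirical covariance between sources,
realistic MRI spatial structure, longitudinal trajectories, missingness
(the data model is deliberately complete-case and rejects missing cells),
non-Gaussian marginals beyond what the optional `log1p` path addresses.
Consequently, passing tests demonstrate the correctness and honesty of
the pipeline — leakage-free estimation, calibrated probabilities on
self-consistent generators, recovery of planted structure — not the
clinical performance to expect on real cohorts.

## 7. Numerical choices and degenerate inputs

- Truncated-normal draws clamp quantiles to `[1e-12, 1 − 1e-12]` so the
  sampler stays finite under extreme separation.
- Zero-variance features standardize to 0 with a warning; constant
  vectors discretize to a single bin with a warning; `0·log 0 := 0`
  throughout the information estimators.
- Composite kernels are checked for positive semi-definiteness (minimum
  eigenvalue ≥ −1e−6) before fitting; simplex violations beyond 1e−8 are
  fatal.
- Ties: JMI ranking breaks to the lowest feature index; `D_optimal`
  breaks to the smallest count; the binary decision at exactly the
  threshold goes to non-progressor with a flag.
- Degenerate test inputs (zero-variance difference vectors, empty
  strata, absent classes) are flagged, never silently dropped.
- Seeds: every stochastic component takes an explicit integer seed;
  derived child seeds stay below 2³¹.

## 8. Known limitations

The sampler's plug-in prediction uses posterior means of `W` and `β`
rather than averaging the probit probability over the posterior — a
standard but approximate choice. The corrected CV t-test's degrees of
freedom follow the cited r-df calibration, which is itself approximate
for small r. Calibration requires all ten probability sub-intervals to be
occupied; small cohorts with concentrated predictions will report CCC as
unavailable. The multiple-kernel presets group kernels by source after
joint feature selection; other compositions are expressible through
explicit `kernel_spec` lists but not named presets. No imputation layer
is provided by design.
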