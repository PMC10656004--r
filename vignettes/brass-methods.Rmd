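---
title: "Resampling binary traits in structured samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling binary traits in structured samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brass)
```

## The problem

Permutation testing estimates the null distribution of a test statistic by
regenerating the trait under the null hypothesis. Its justification is
exchangeability of the subjects, which fails in genetic association studies
whenever population structure, family relatedness or cryptic relatedness
correlates the phenotype across individuals: naively permuting a structured
trait destroys its correlation and typically inflates the type 1 error of
empirical significance thresholds. For quantitative traits a linear mixed
model (LMM) can be used to decorrelate residuals before permuting. A binary
trait adds a second obstacle: its variance is tied to its mean,
`Var(Y_i) = mu_i (1 - mu_i)`, and covariates act on a nonlinear (logit)
scale, so an LMM misspecifies exactly the features that matter.

This package generates null replicates of a correlated binary trait with a
quasi-likelihood model that keeps both features, and evaluates the
resulting empirical genome-wide thresholds in simulation against six
alternative resampling strategies.

## The quasi-likelihood null model

Only the first two conditional moments of the trait are specified:

* mean: `mu = logit^-1(X beta)`, with `X` an `n x k` covariate matrix
  including an intercept;
* variance: `Omega = Gamma^1/2 Sigma Gamma^1/2`, with
  `Gamma = diag(mu_i (1 - mu_i))` and `Sigma = xi Phi + (1 - xi) I`.

`Phi` is a genetic relatedness matrix (GRM) or kinship matrix and
`xi in [0, 1]` acts as a heritability parameter: it mixes the
relatedness-driven covariance into an otherwise independent working
structure. `(beta, xi)` are estimated by `fit_null_model()`, which
alternates Fisher scoring on `beta` (holding `xi`) with one-dimensional
root-finding for the `xi` moment equation on `[0, 1]` (holding `beta`).
Numerical choices, made here because the estimating equations do not
dictate a schedule:

* a single eigendecomposition of `Phi` is taken up front, so every
  `Sigma(xi)` factorization, inverse action and determinant is `O(n^2)`;
  the decomposition can be passed in (`eigen_phi`) and shared across fits;
* convergence is declared when the largest change in `beta` and in `xi`
  falls below `1e-6` (at most 100 outer iterations), after which `beta` is
  polished at the final `xi` until the quasi-score is zero to near machine
  precision — the identity-permutation exactness of the replicates is
  limited by this score residual, not by linear algebra;
* fitted means are clamped to `[1e-10, 1 - 1e-10]` to keep `Gamma`
  invertible; clamped fits raise a separation warning;
* if the moment equation for `xi` has no sign change on `[0, 1]`, the
  boundary with the smaller residual is taken and reported; when `Phi` is
  numerically the identity the equation is degenerate and `xi = 0` by
  convention (the fit then equals the ordinary logistic MLE);
* initialization: `beta` from plain logistic regression, `xi = 0.5`.

## The decorrelating transform and replicates

With `C` such that `C^T C = Omega_hat` (built as
`diag(sqrt(lambda)) U^T Gamma_hat^1/2` from the eigendecomposition
`Sigma_hat = U diag(lambda) U^T`), the residual `Y - mu_hat` has
approximate covariance, after whitening,

```
Var[C^-T (Y - mu_hat)] ~ I - W (W^T W)^-1 W^T,   W = C^-T Gamma_hat X,
```

a symmetric idempotent matrix of rank `n - k`: whitening removes the
polygenic correlation, and the residual rank deficiency reflects the `k`
estimated mean parameters. An orthonormal basis `V` of the orthogonal
complement of `W`'s column space — taken from the trailing columns of the
full QR decomposition of `W`, `O(n^2 k)`, without materializing the
projector — maps the residual to
`zeta = V^T C^-T (Y - mu_hat)`, whose entries share their mean and
variance and are approximately uncorrelated (second-order
exchangeability). Replicates permute `zeta` and back-transform:

```
Y_pi = mu_hat + C^T V  Pi  V^T C^-T (Y - mu_hat).
```

The identity permutation returns `Y` exactly; replicates are real-valued.
Only `V V^T` is identified — any orthogonal rotation of `V` gives the same
projector — so no result may depend on a particular basis, and the tests
compare replicate sets only through rotation-invariant quantities or
against oracles that retrace the same factorization convention.

`generate_replicates()` draws independent uniform permutations from a
seeded generator local to the replicate set (the caller's RNG stream is
saved and restored), and accepts an explicit permutation list, which is how
the small-`n` exhaustive enumerations in the test suite are driven.

## Comparator methods

Six alternatives are implemented behind the same `resample_traits()`
front-end:

* **naive** — REML LMM fit `Y = X beta + e`,
  `e ~ MVN(0, sigma1^2 Phi + sigma2^2 I)` (profiled over the mixing
  proportion on one eigendecomposition), then plain permutation of the
  residuals. REML rather than ML matches the convention of the Gaussian
  residual-permutation literature. When `Phi` is the identity the split of
  the two components is unidentifiable and the `Phi` component is set to
  zero by convention.
* **mvnpermute** — the Gaussian analog of the transform above with
  `Gamma` replaced by the identity: whiten the LMM residuals by a
  factorization of `sigma1^2 Phi + sigma2^2 I`, project out the covariate
  directions, permute, back-transform.
* **logmm_pql** — a logistic mixed model
  `logit(m) = X beta + u`, `u ~ MVN(0, sigma^2 Phi)`, fitted by penalized
  quasi-likelihood (PQL): a working-response linear mixed model with
  weights `m (1 - m)` alternates with a one-parameter REML update of
  `sigma^2`. The working model's Bernoulli dispersion is fixed at 1 — the
  REML criterion must not profile a free scale, which would let `sigma^2`
  drift to absurd values. Binary replicates are then drawn from the fitted
  model. PQL is known to bias `sigma^2` downward for binary traits; the
  sampler inherits the bias and its thresholds inflate when polygenic
  effects dominate, which is the qualitative pattern the comparison
  experiment checks.
* **brass_mod / mvnpermute_mod / naive_mod** — the real-valued replicates
  thresholded so that each replicate has exactly the observed number of
  cases; ties at the threshold break by stable sample-index order.

## Single-marker test and replicate scans

`carat_test()` implements a retrospective quasi-score test. The score for
the marker effect uses the quasi-score Jacobian `Gamma G`, giving
`S = G^T R` with `R = Gamma_hat Omega_hat^-1 (Y - mu_hat)`; the estimating
equation for `beta` makes `R` exactly orthogonal to `X`, so genotype
components aligned with the covariates — the intercept, the removed
principal components, any ancestry covariates — cancel from the score.
Treating the genotype as random given the trait with covariance
`sigma_g^2 Phi_adj`, the statistic `T = S^2 / (sigma_g^2 R^T Phi_adj R)`
is referred to chi-square with 1 df. Two variance estimators are provided:
the allele-frequency form `2 f (1 - f)` and the structure-adjusted form
`G^T P G / (n - D - 1)` with
`P = A^-1 - A^-1 Z (Z^T A^-1 Z)^-1 Z^T A^-1`, `A` the PC-adjusted GRM and
`Z` the removed eigenvectors plus an intercept column (the default).

The structure-adjusted estimator inverts the adjusted GRM, which makes it
sensitive to GRM conditioning: it requires the GRM to be built from many
more markers than samples. With `M` markers, GRM sampling noise inflates
the estimator by a factor of roughly `1 + n/M`, and a rank-deficient GRM
(`M < n`) is unusable for it — the near-null directions, completed by the
ridge, dominate the quadratic form. The simulation designs in this package
keep `M > n` wherever this estimator's own calibration is the quantity
being measured; the threshold procedure itself is self-calibrating in this
respect, because observed data and replicates are scanned identically.

Replicate scans (`scan_min_p()`) reuse the observed-data null fit. For the
real-valued permutation replicates this is exact, not an approximation:
`X^T Gamma_hat Omega_hat^-1 (Y_pi - mu_hat) = W^T V Pi zeta = 0` for every
permutation, so each replicate satisfies the reused fit's score equation
identically. Binary resampled replicates (the PQL sampler, the `_mod`
variants) carry their own realized random-effect structure, which a reused
fit would misread as association; they are refitted per replicate
(automatically, via the replicate set's binary flag) and scanned with
their own null fits, mirroring how the observed data are analyzed.

## GRM utilities

`compute_grm()` is the standard centered-and-scaled estimator over
polymorphic markers. `remove_top_pcs()` removes the top `d` eigenvectors
by symmetric projection and restores positive definiteness with a `1e-6`
ridge; because the projector uses the GRM's own eigenvectors, the adjusted
GRM keeps the same eigenvectors with the top `d` eigenvalues replaced by
the ridge, and the cached decomposition is reused by every downstream fit
at no extra cost. The removed PCs are returned for use as fixed-effect
covariates. `loco_grms()` builds leave-one-chromosome-out GRMs so that
replicates for a chromosome are never informed by its own markers.

## The synthetic-data generator

The generator reproduces the simulation design the experiments are run
under; its defaults are the study conditions, not tuning knobs.

* **Allele frequencies** — two subpopulations under the Balding-Nichols
  model with `F = .01`; ancestral frequencies uniform on `(.2, .8)`.
* **Pedigrees** — replicated three-generation pedigrees: two founder
  couples, two children per couple, each child marrying a founder-like
  spouse drawn from the same subpopulation, two grandchildren per couple —
  20 members. Equal numbers of pedigrees per subpopulation; founder
  genotypes are drawn from the subpopulation frequency and descendants by
  gene dropping (one allele per parent, independently per marker; no
  linkage). Samples of roughly 200 use ten pedigrees.
* **Covariates** — standardized uniform age, Bernoulli(.5) sex, and an
  i.i.d. standard normal covariate (the one dropped in
  missing-covariate scenarios — from the analysis only, never from
  generation).
* **Trait models** — logistic,
  `Y_i ~ Bernoulli(logit^-1(X_i beta + W_i alpha))`, or liability
  threshold, `Y_i = 1{X_i beta + W_i alpha + eps_i > 0}`, with `W` the
  standardized causal genotypes and `alpha ~ MVN(0, sigma^2 I)`,
  `sigma_a^2 = sigma^2 M_c`.
* **Calibration** — `calibrate_trait_model()` chooses the intercept, the
  covariate effects and `sigma_a^2` so that (i) covariates explain a fixed
  fraction (20-80%) of `Var(X beta + W alpha)`, (ii) the Bernoulli-error
  share of the total phenotypic variance, `E[p(1-p)] / Var(Y)`, hits 20%
  (scenario a, prevalence 30%) or 55% (scenario b, prevalence 5%), and
  (iii) the prevalence hits its target. The two free scales solve by
  nested one-dimensional root-finds over a fixed Monte-Carlo sample
  (`1e5` draws by default), using an i.i.d. normal stand-in for the
  marginally normal polygenic term; the solution is deterministic given
  the calibration seed. Note that fixing the error share on the observed
  scale at 30% prevalence forces `Var(Y) = .21` and `E[p(1-p)] = .042`,
  so the success probabilities are pushed toward 0 and 1 and the implied
  linear-scale variance is large (about 65); the trait is then strongly
  structured, which is the confounding regime the resampling methods are
  meant to survive. The normal covariate's effect is set by a first-order
  Wald rule, `beta_norm = z_.975 sd(Y) / (E[mu(1-mu)] sqrt(n_ref))` with
  `n_ref = 1000`, targeting an average mixed-model Wald p-value of .05; a
  stochastic root-find over repeated LMM fits would add cost without
  affecting any measured quantity (this covariate carries about 2% of the
  linear variance).
* **Ascertainment** — `ascertain_sample()` retains exact case/control
  counts (e.g. 500/500, or 300/700). `simulate_dataset()` sizes the source
  population from the calibrated prevalence with a 20% margin and regrows
  it once if a tail event leaves it short.

What the generator does **not** emulate: linkage disequilibrium between
markers, genotyping error, X-linked markers, age/sex effects on
ascertainment, or non-random mating. Passing tests therefore demonstrate
correct behavior under idealized structure of the kind the model is built
for, not robustness to every feature of real cohort data.

## The threshold experiment

`run_type1_experiment()` reproduces the four-stage design: simulate a
dataset; build the GRM from the causal markers, remove the top PC
(`D = 1`) and pass it to every method as a covariate; fit the null model;
record the observed minimum quasi-score p-value over the null markers;
generate `L` replicates per method and record each replicate's minimum
p-value; estimate the per-dataset threshold as the `ceiling(alpha L)`
order statistic of the replicate minima; and compare the observed minimum
to the threshold across datasets. The empirical rejection rate is reported
with the binomial z-test bounds
`alpha +/- 1.96 sqrt(alpha (1 - alpha) / N)` and a verdict (inflated /
well-controlled / conservative). Per-dataset seeds are pre-drawn from the
master seed, so results are identical whether datasets run serially or
not, and failures in single datasets are recorded and skipped.

An optional adaptive rule (off by default) stops replication for a dataset
when a two-sided 99.99% binomial confidence interval for its permutation
p-value excludes `alpha`; the paired full-versus-adaptive check in the
test suite bounds the bias this introduces.

## Problem sizes used in the checks

A full-scale evaluation of this kind (20,000 datasets by 10,000
replicates per setting, nominal level `10^-3`) is a cluster-month, far
beyond a single-machine test suite; the package's own checks use designs
whose Monte-Carlo error is small enough to detect the failure modes of
interest:

* headline threshold calibration: 1,000 datasets x 500 replicates at
  `alpha = .01`, `n = 200` (ten pedigrees), 500 causal markers, 20 null
  markers, logistic 40/60 split at prevalence 30% — the binomial band is
  `.01 +/- .0062`;
* generative-model calibration: 100,000 individuals;
* second-order exchangeability of `zeta`: 20,000 regenerated traits with
  per-replicate refits at `n = 96`, against an exact-moment
  block-exchangeable binary generator (the quasi-likelihood model is not
  fully generative, so the generator matches its first and second moments
  exactly rather than sampling from a particular third-moment choice);
* quasi-score calibration at nominal .05: 200 datasets of `n = 160` with
  8,000-marker GRMs (`M >> n`, see above), 20 markers each, judged by a
  cluster-robust z-interval;
* comparative directions at `alpha = .05`: 300 paired datasets x 200
  replicates (PQL versus the quasi-likelihood transform at an 80%
  polygenic share) and 500 datasets x 300 replicates (Gaussian
  permutation at an 80% covariate share). At the headline nominal level
  .01, the conservative method's rejection bound would sit within
  Monte-Carlo noise of zero at these dataset counts; .05 gives the same
  qualitative contrast with usable power.

## Known limitations

* The structure-adjusted genotype-variance estimator degrades when the
  GRM marker count is not much larger than the sample size (see above);
  the allele-frequency estimator is available where that regime cannot be
  met.
* PQL fitting is approximate by construction; its known downward variance
  bias is a property being studied, not corrected.
* The transform guarantees second-order exchangeability only; higher
  moments of the binary trait are not preserved in real-valued
  replicates, and the thresholded `_mod` variants restore binaryness but
  not the fitted covariance. Their type-1-error behavior is part of the
  comparison, not an accident.
* Replicates are generated under the null only; power analysis and effect
  estimation are out of scope, as are exact enumeration p-values,
  dominance or multi-component covariance structures, and
  unrelated-subset PC pipelines.

## A minimal session

```{r example, eval = FALSE}
spec <- calibrate_trait_model(covariate_fraction = 0.4, scenario = "a")
sim <- simulate_dataset(spec, n_pedigrees = 10, seed = 11)
grm <- compute_grm(sim$causal)
struct <- remove_top_pcs(grm, d = 1)
x <- cbind(intercept = 1, struct$pcs, age = sim$covariates$age,
           sex = sim$covariates$sex, norm = sim$covariates$norm)
fit <- fit_null_model(sim$y, x,
                      eigen_phi = list(vectors = struct$eigvecs,
                                       values = struct$adj_eigvals))
reps <- generate_replicates(sim$y, fit, build_transform(fit),
                            n_reps = 500, seed = 3)
minp <- scan_min_p(reps, sim$null_markers, struct, fit)
estimate_threshold(minp, alpha = 0.01)
```
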