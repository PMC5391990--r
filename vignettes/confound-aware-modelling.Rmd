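---
title: "Confound-aware predictive modelling from biased samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confound-aware predictive modelling from biased samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconfound)
```

## The problem

When a regression model is trained to predict a clinical score or age from
high-dimensional imaging features, the training sample often contains an
association between the target and a nuisance variable — gender, acquisition
site, medication — that is absent from the population over which the model
will actually be applied. We call such a variable a *confound*: it affects
the features, and its sample association with the target is not
representative of the population-of-interest. A training sample carrying
such an association is *biased*.

Bias of this kind induces covariate shift: the joint distribution of the
predictors in the training sample differs from the population. Combined with
model misspecification — unavoidable in exploratory imaging analyses — it
degrades predictions on unbiased data and, more subtly, redistributes the
errors so that one confound group is predicted better than the other over
parts of the target range.

`deconfound` implements four strategies behind one train/predict interface,
together with the evaluation machinery needed to study them honestly
(biased training / unbiased testing, balanced and signed group-difference
error metrics, and a restricted permutation test).

## Models

All four strategies use Gaussian-process regression with a zero prior mean.
The homoscedastic Gaussian likelihood has noise scale $\sigma$, and the
posterior predictive mean at a test point $x_*$ is the kernel ridge
regression prediction
$$\bar y_* = k_*(K + \sigma^2 I)^{-1} y,$$
with variance $k(x_*, x_*) - k_*(K + \sigma^2 I)^{-1}k_*^T + \sigma^2$.
Hyperparameters are estimated by maximising the log marginal likelihood
$$\log Z = -\tfrac12 y^T A^{-1} y - \tfrac12 \log|A| - \tfrac n2 \log 2\pi,
\qquad A = K(\theta) + \sigma^2 W.$$

* **Images only** (`images_only`). Linear-plus-bias kernel on the
  standardized features, $k(x_i, x_j) = g_i g_j^T / l^2 + b^2$: a linear
  model of the features, the default when confounding is ignored.
* **Adjusted images** (`adjusted_images`). Every feature is first
  residualised on the intercept-augmented confounds,
  $G^A = G - \hat C(\hat C^T \hat C)^{-1}\hat C^T G$ (per-feature ordinary
  least squares), then modelled as above. By default the adjustment model is
  fit transductively on the pooled training and test rows; a train-only
  variant (fitting on a subset $S$) is available because deployment cannot
  see test data.
* **Images & confounds** (`images_confounds`). The confounds are appended to
  the features and the kernel becomes the sum of the linear-plus-bias kernel
  on the feature block and a linear automatic-relevance-determination (ARD)
  kernel $c_i \Lambda_{ARD} c_j^T$ on the confound block,
  $\Lambda_{ARD} = \mathrm{diag}(1/l_1^2, \ldots)$, so the marginal
  likelihood controls each confound's contribution. The linear ARD kernel is
  appropriate for continuous confounds and discrete ones with two levels
  (encoded 0/1); an ARD squared-exponential kernel over a one-hot encoding
  is provided for more levels but is outside the tested surface.
* **Instance weighting** (`instance_weighted`). Each training subject is
  weighted by the density ratio
  $$w_i = \frac{\hat P(y_i)}{\hat P(y_i \mid c_i)},$$
  which follows from empirical risk minimisation when the risk is taken over
  a population in which target and confound are independent: subjects whose
  target is typical of their confound group in the biased sample are
  down-weighted. Both densities are estimated with small GPs — a bias-only
  kernel for the marginal (effectively a fitted normal) and a bias + ARD
  kernel on the confounds for the conditional — each evaluated as the
  posterior predictive density at the training points themselves (in-sample,
  accepting the optimism this implies). The weighted model uses the
  heteroscedastic likelihood with per-point noise $\sigma^2 / w_i$, so the
  predictive mean becomes $k_*(K + \sigma^2 W)^{-1} y$ with
  $W = \mathrm{diag}(1/w_i)$: a weighted kernel ridge regression. The
  predictive function does not depend on the confounds.

A note on the heteroscedastic noise convention: writing the per-point scale
as $\sigma_i = \sigma w_i$ is inconsistent with the predictive formula
above, which requires $\sigma_i^2 = \sigma^2 / w_i$ (a *higher* weight must
mean *lower* noise, i.e. more influence, to reproduce the weighted-loss
interpretation). We implement $\sigma_i^2 = \sigma^2 / w_i$ throughout so
the predictive identity holds exactly; the unit test on duplicated points
(weight 2 equals two unit-weight copies) pins this down.

### Balance diagnostics

Whether the weights actually de-bias the sample is checked with the weighted
standardized difference of the target across the two confound levels,
$$\frac{m^{Wtd}_{Y_0} - m^{Wtd}_{Y_1}}
       {\sqrt{(s^{2,Wtd}_{Y_0} + s^{2,Wtd}_{Y_1})/2}},$$
using frequency-weighted means and unbiased sample variances
(`weighted_standardized_difference()`). With equal weights this reduces
exactly to the classical standardized difference. The variance formula is
implemented with squared deviations — the only dimensionally consistent
reading of the estimator.

## Evaluation protocol

Cross-validation is inappropriate here: the test fold must be an *unbiased*
sample of the population-of-interest, which a held-out part of a biased
sample is not. `run_protocol()` therefore:

1. half-splits a population pool (target and confound independent) into two
   folds;
2. draws `J` training samples from each fold — *biased* draws use selection
   probabilities $\propto \exp(\lambda\, z(y_i)\, \tilde c_i)$ and are
   redrawn until a two-sided equal-variance t-test of the target across
   confound levels is significant at 0.05; *unbiased* draws are uniform and
   must be non-significant;
3. trains each strategy on each sample and predicts the opposite fold;
4. computes, per run: the MSE; the group-balanced MSE (each subset of the
   target range contributes the unweighted mean of its two group MSEs,
   subsets then averaged with weights $n_l/|F|$); and the signed
   group-difference errors (level-0 MSE minus level-1 MSE per subset, with a
   subset-size-weighted absolute summary). The target partition threshold is
   the pool median, with ties falling in the low subset.

The exponential-tilt selection model is this package's concrete choice — the
source protocol states only non-uniform sampling preferring a
confound–target relationship. It is smooth, direction-controllable, and
reduces to uniform sampling at $\lambda = 0$. An optional constraint keeps
the per-level counts near a target ratio (off by default), emulating cohorts
whose confound levels are unbalanced by design.

### Restricted permutation test

`restricted_permutation_test()` shuffles the targets *within confound
level*, separately within each training sample and each test fold. This
preserves the confound–target association while severing the
feature–target link, so it tests whether the model learns information from
the features *beyond* the confound — a model that merely reads the confound
off the features passes an ordinary permutation test but fails this one.
The p-value counts permutations (the identity included, so
$p \ge 1/N_{perm}$) whose metric is at most the observed one, divided by
the total (500 by default). With `fixed_hyperparameters = TRUE` the kernel
hyperparameters are estimated once and only the linear solve is repeated
per permutation, which keeps large permutation counts cheap and — when
combined with `optimize = FALSE` and preset hyperparameters — makes the
permutation distribution exactly exchangeable.

## Synthetic data: what it emulates and what it does not

`simulate_population()` generates the structure the analysis assumes:
targets drawn independently of a two-level (or continuous) confound, and
features
$$G = y\,a^T + \tilde c\,d^T + E, \qquad E_{ij} \sim N(0, \sigma_n^2),$$
so the confound genuinely affects the features while the population is
unbiased. Defaults (400 subjects, 300 features, a 10%-sparse signal of one
noise-sd per loaded feature, a confound effect of one noise-sd on half the
features, an even two-level confound) emulate a several-hundred-subject
structural-imaging pool at desk scale. What the generator does **not**
emulate: spatial covariance and smoothness of real images, site-specific
variance components, non-Gaussian score distributions, or nonlinear
confound effects (a hook exists but is untested surface). A green test
therefore establishes the *logic* of the methods under the stated
linear-Gaussian world, not their behaviour on real imaging data — the
linear-Gaussian family matches the models themselves, all of which use
linear kernels.

### The misspecification demonstration

`simulate_misspecification_demo()` isolates the interaction of covariate
shift and misspecification with one feature and one confound. A latent
trait $h \sim N(0,1)$ drives both sides:
$$g = h + \gamma \tilde c + \epsilon_g, \qquad
  y = h + \delta(h^2 - 1) + \epsilon_y.$$
At $\delta = 0$ the joint law of $(g, c, y)$ is Gaussian, so the
least-squares model `y ~ g + c` is correctly specified; at $\delta > 0$
every linear candidate is misspecified.

Two design points matter and were chosen deliberately:

* **Biased draws tilt on the feature, not the target.** Selection that
  depends on the target changes $P(y \mid g, c)$ between sample and
  population, so even a correctly specified model converges to a shifted
  regression function and the "correct specification protects you" claim
  fails *by construction*, for reasons unrelated to covariate shift.
  Tilting on $g$ plants the same confound–target association as covariate
  shift proper, preserving $P(y \mid g, c)$ — the regime the claim is
  about. (The main protocol keeps target-tilted draws: there the point is
  to emulate a recruitment process in which, say, one gender is more likely
  to be sampled as the score increases.)
* **Scale.** `misspecification_contrast()` is run at a population of 1600
  with training draws of 150 for the acceptance checks. At small test folds
  the Monte-Carlo noise of a quadratic target's squared errors, and at
  small training draws the design-extrapolation variance of least squares
  (which penalises biased training even under correct specification),
  both dominate the asymptotic contrast the demonstration is about.

## Numerical choices

* Standardization uses training-set statistics only, with the sample
  (n − 1) standard deviation; constant training features map to all-zero
  columns rather than being dropped, so weight-map indexing is stable.
  For the adjusted-images strategy, features are adjusted first and
  standardized after.
* Hyperparameters are optimised in log space (positivity without bounds) by
  BFGS with analytic gradients, from three deterministic restarts around
  data-scale initial values ($l_0 = \sqrt{\text{mean squared row norm}}$,
  $b_0 = \mathrm{sd}(y)$, $\sigma_0 = \mathrm{sd}(y)/2$; log-offsets
  $0, +1, -1$); the best restart is kept. Derivatives of the evidence under
  the heteroscedastic likelihood are the standard Gaussian identities with
  $\sigma^2 I$ replaced by $\sigma^2 W$, and are validated against central
  finite differences in the tests.
* Cholesky factorisations use adaptive jitter starting at
  $10^{-10} \cdot \text{mean diag}$, doubling at most ten times.
* Instance weights are rescaled to mean 1 by default (keeps $\sigma^2$
  comparable with the unweighted model); raw ratios and an optional
  percentile clip are available but off, since constraining weights is
  deliberately left outside the evaluated surface. Non-finite ratios are an
  error (a finite-ratio guard stands in for the formal support condition of
  importance weighting).
* Two-level confounds are encoded 0/1 in a single column; continuous
  confounds are standardized inside `images_confounds` while 0/1 encodings
  are left unscaled, so the ARD scale of a binary confound is interpretable
  on the level difference.
* Missing values are rejected, never imputed.

## Known limitations

* Density-ratio weights are evaluated in-sample; with very small samples the
  optimism of in-sample predictive densities can flatten the weights.
* The adjustment model is linear; if the confound acts nonlinearly on the
  features, residualisation can worsen rather than remove bias (the
  evaluation protocol is designed to reveal exactly this).
* On-disk NIfTI volumes are not read directly; `flatten_volumes()` expects
  arrays already in memory, and the tabular formats are the supported
  interchange. Masked flattening uses column-major (array scan) order.
* No sparse/approximate GP machinery: training samples beyond a few
  thousand subjects are out of scope.

## A worked run

```{r, eval = FALSE}
pool <- simulate_population(n = 400, d_features = 300, seed = 1)
pr <- run_protocol(pool,
                   strategies = c("images_only", "adjusted_images",
                                  "images_confounds", "instance_weighted"),
                   J = 2, sample_size = 100, biased = TRUE, seed = 1)
pr$summary
autoplot(pr, type = "signed")
```

The same computation, driven from the shell, is
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`, or
through the CLI: `deconfound simulate`, `deconfound evaluate`,
`deconfound permtest` (see `?deconfound_main`).
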