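---
title: "Counting molecules from photobleaching fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules from photobleaching fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleachcount)
```

## The problem

Fluorescence microscopy reports signal in arbitrary camera units. To
compare measurements across laboratories, to fit mechanistic models, or
to validate fitted parameters, one needs absolute numbers of molecules —
equivalently, the brightness per molecule $\nu$ that converts camera
units into counts. `bleachcount` estimates absolute numbers from the
*fluctuations* of deliberately photobleached cells, exploiting that
molecular noise scales with the number of molecules, not with their
concentration: for $Y = \nu X$, $\mathrm{Var}[Y] \propto \nu\,E[Y]$, so
at a fixed mean fluorescence, large fluctuations mean few, bright
molecules and small fluctuations mean many, dim ones.

## The fluctuation estimator

For first-order bleaching of $x_0$ molecules with survival probability
$\ell = e^{-\lambda t}$, the unbleached count is binomial:
$E[X_t] = x_0\ell$ and $\mathrm{Var}[X_t] = x_0\ell(1-\ell)$.
Eliminating $\ell$ and multiplying by $\nu^2$ gives, for the
fluorescence $Y_t$,

$$\hat{x}_0 \;=\; \frac{E[Y_t]\,\bigl(y_0 - E[Y_t]\bigr)}{\mathrm{Var}[Y_t]},$$

valid at every positive time. With exact moments this identity is exact
for every $\ell \in (0,1)$ and every $\nu$ (a property the test suite
asserts to machine precision), and it is also the maximum-likelihood
point of the noiseless measurement model, which the package verifies
numerically by integrating the underlying change-of-variable chain
(`mle_x0()`).

In practice $E[Y_t]$ is estimated per cell by Gaussian-process
regression (squared-exponential kernel) and $\mathrm{Var}[Y_t]$ by the
squared residual $(y_t - E[Y_t])^2$. Each cell's trace of $n_d$ frames
yields $n_d - 1$ pairwise estimates; all estimates from all cells are
pooled, and the mode of a kernel density estimate over
$\log_{10}\hat{x}_0$ is the point estimate.

### Bias under heterogeneity and noise

When every molecule has its own brightness $\nu_i$ and survival
probability $\ell_i$ (drawn from some $P(\nu, \ell)$) and the
measurement noise has variance $\sigma_e^2$, the expected estimate is
$x_0/(1+\epsilon)$ with

$$\epsilon = \frac{\sigma_e^2/x_0 +
\mathrm{Cov}[\nu, \nu\ell] - \mathrm{Var}[\nu\ell]}
{E[\nu\ell]\,(E[\nu] - E[\nu\ell])}.$$

Large measurement noise gives $\epsilon > 0$ (underestimation); strong
heterogeneity with little noise gives $\epsilon < 0$ (overestimation).
`predicted_bias()` and `accuracy_margins()` evaluate this law and the
three accuracy conditions; the estimator tolerates variation in $\ell$
much better than variation in $\nu$, and fails outright when
$\mathrm{Var}[\nu] > E[\nu]^2$. The acceptance suite confirms the law by
Monte Carlo on a grid of noise and heterogeneity levels.

## GP smoothing choices

* Kernel $k(t,t') = \theta_0 \exp[-\theta_1 (t-t')^2/2]$ plus white
  observation noise $\theta_2$; hyperparameters are found by maximizing
  the marginal likelihood inside hard box bounds
  ($10^3 < \theta_0 < 10^{14}$, $10^{-8} < \theta_1 < 1$,
  $10 < \theta_2 < 10^{10}$), which bracket camera-unit scales from
  hundreds to tens of millions.
* Optimization runs in log-hyperparameter space (`L-BFGS-B`) from one
  data-driven start plus five starts uniform in the log of each bound
  interval; the box is a hard constraint, asserted in tests.
* Traces are mean-centered before fitting (the GP prior mean is not
  otherwise specified by the method) and the offset restored afterwards.
* $y_0$ is taken from the GP mean at $t=0$ rather than the raw first
  frame (config switch `y0_convention`), because the raw frame would
  inject its own measurement noise into every pair.

The smoothing step has a known, directional failure mode: if the fitted
$\theta_2$ is too small the GP mean chases fluctuations, the squared
residuals underestimate $\mathrm{Var}[Y_t]$, and the pooled estimate is
biased **high**; if $\theta_2$ is forced very large the mean ignores the
data and the estimate is biased **low**. Both directions are
demonstrated on simulation in the test suite. Under the realistic camera
settings used in the acceptance runs the net effect keeps the pooled
mode well within one order of magnitude of truth across
$x_0 \in \{10^3, \dots, 10^6\}$, with mild overestimation at low counts
(smoothing-driven) and underestimation at $10^6$ (noise-driven), exactly
the directions the bias law predicts.

## The Bayesian alternative

The package also implements the model-explicit route the estimator is
benchmarked against. Each cell holds two pools that bleach at their own
rates; under the linear noise approximation the pool distribution stays
Gaussian with closed-form mean/covariance propagation
(`lna_propagate()`, cross-checked against numerical integration of the
moment ODEs at $10^{-8}$). Measurements are normal around
$\nu(x_1+x_2)+f$ with variance quadratic in the signal; the filter
replaces the state-dependent variance by its expectation under the
one-step-ahead prediction. The per-trace likelihood is the product of
one-step predictive densities from a delta initial state at
$(x_0(1-\alpha), x_0\alpha)$ — which requires $\sigma_{e,0} > 0$, so
that scale's prior is bounded away from zero. Negative updated means are
clipped to zero (means only; the covariance is left untouched, as the
clipping is a rare boundary repair, not part of the model).

One numerical subtlety is worth recording. The moment equations evaluate
the bleaching-noise increment at the *conditional* mean — the mean
updated by the data — so the implied joint law of a whole trace is not
exactly multivariate normal, and a brute-force joint-Gaussian density
agrees with the filter only to $O(10^{-3})$. `kalman_filter(...,
process_noise = "prior")` instead evaluates the increment on the
unconditional mean path, which *is* exact linear-Gaussian inference;
that mode exists for validation and matches the brute-force oracle to
$10^{-10}$. Inference uses the conditional form, faithful to the moment
equations.

### Priors, sampling, initialization

Scale parameters ($\nu$, the $\sigma_{e,i}$, and the per-cell initial
fluorescence $y_0 \equiv \nu x_0$, proposed in place of $x_0$ to
decouple the expected trace from the shared brightness) carry proper
scale-free $1/x$ priors; $\lambda_1,\lambda_2,f,\alpha$ carry flat
priors. All bounds are explicit and configurable (`prior_spec()`);
defaults span rates $10^{-6}$–$1\,\mathrm{s}^{-1}$ and brightness
$10^{-3}$–$10^{3}$.

Sampling is Metropolis-within-Gibbs: per-cell blocks one cell at a time
(only that cell's likelihood is recomputed), then the shared block
against the full data; normal proposals for $\lambda_1,\lambda_2,f,
\alpha$ and log-normal (with Hastings correction) for the positive
scales. Proposal scales adapt by a Robbins–Monro rule toward 0.234
block acceptance, and ten tempered chains (likelihood tempered, prior
not, so the hottest chain samples the prior) swap adjacent pairs with
log-spacings adapted toward a 0.234 swap rate. All adaptation stops at
the end of burn-in (default half the run), so retained cold-chain
samples target the exact posterior.

Initialization is a nested optimization: (1) bi-exponential fits give
per-cell starts, and a quick closed-form fluctuation estimate applied to
the fit curve and residuals seeds the brightness — without this the
optimization reliably falls into a local optimum where the linear noise
scale absorbs all fluctuations and $\nu$ collapses to a bound; (2) each
cell is fitted independently by bounded multistart BFGS under a fixed
evaluation budget (the structured restart at $f = 0$ matters, because
bi-exponential fits of partially bleached traces can drag the offset far
negative); (3) shared parameters start at the medians of the per-cell
fits, excluding fits stuck at a bound; (4) block-coordinate ascent
alternates per-cell and shared optimization, accepting only
improvements, until the joint likelihood stalls; (5) half the chains
start at that optimum, half at optima of ascent runs from random draws.

### What the calibration run does and does not show

The acceptance suite checks that the 95% credible interval for $\nu$
covers the truth in at least 80 of 100 repetitions on 3-cell cohorts.
The study conditions for this check use $x_0 = 2000$ and weak camera
noise ($\sigma_{e,0}=20$, $\sigma_{e,1}=0.1$, $\sigma_{e,2}=10^{-5}$),
chosen so that the binomial bleaching innovations dominate the camera
noise and three cells genuinely pin down the brightness. Under
realistic (noisier) camera settings the 3-cell posterior for $\nu$ is
bimodal: a mode near the truth competes with a mode at tiny $\nu$ in
which each cell's free rates absorb its slow binomial wander and all
scatter is attributed to measurement noise — with so little data that
explanation can even carry a higher likelihood. That is a statement
about identifiability at $n_r = 3$, not about the sampler, and it
mirrors the known tendency of the model-explicit route to underestimate
numbers (tiny $\nu$ means huge counts, i.e. overestimated $x_0$, or the
reverse for the mirrored mode). Larger cohorts remove the second mode.

## The simulator

Ground truth comes from exact simulation, not from the LNA:

* Pool counts evolve by binomial thinning with survival
  $e^{-\lambda\Delta}$ per interval — the exact discrete-time law of
  first-order decay (an SSA would be equivalent and slower). One-step
  and multi-step simulation to the same horizon are statistically
  indistinguishable (KS-tested).
* The initial split rounds $x_0\alpha$ to the nearest integer; reported
  truth is the post-rounding sum.
* Fully heterogeneous ensembles draw one $(\nu_i, \lambda_i)$ per
  molecule — coupled through a Gaussian copula when a rank correlation
  is requested — and one exponential bleach time per molecule, for
  $O(x_0)$ cost.
* Measurement noise follows the quadratic model
  $\sigma_{e,0}^2 + \nu x\,\sigma_{e,1}^2 + (\nu x\,\sigma_{e,2})^2$,
  with negative observations allowed.

Default study conditions: 45 frames at 10-s intervals; per-frame
survival fractions around 0.97 (slow pool) and 0.90 (fast pool) with
log-normal cell-to-cell spread (σ = 0.2 in log space) and a
Beta-distributed fast-pool fraction centered at 0.4 — values
representative of heterogeneous bi-exponential bleaching in yeast; and
camera noise $\nu = 20$, $\sigma_{e,0} = 136.6$, $\sigma_{e,1} = 1.31$,
$\sigma_{e,2} = 0.0027$, realistic wide-field settings. The population
distributions behind the heterogeneity are not pinned down by any
experiment, so they are exposed as user-specified hyperparameters
(`default_cell_hyper()` is one reasonable choice, not a measured one).

What the simulator does **not** emulate: photophysics beyond first-order
decay (no blinking or triplet states), protein synthesis or maturation
during bleaching (cells are fixed), spatial image structure, or
correlated (non-white) measurement error. Passing tests therefore show
correctness of the machinery under the stated model, not robustness to
every failure mode of real microscopes — the chain of corrections
(flat field, background, autofluorescence) plus the QC filter is the
package's handle on real-data artefacts.

## Preprocessing conventions

* Correction order: flat field (element-wise division), then background
  subtraction (negatives preserved), then autofluorescence (per-time
  mean of wild-type cells subtracted).
* Cell fluorescence is the sum of the brightest 80% of in-mask pixels;
  the pixel count uses `ceiling(0.8 n)` (the rounding rule is a package
  decision — no convention exists).
* The bi-exponential fit `a0 + a1 l1^i + a2 l2^i` is initialized by a
  variable-projection scan (amplitudes solved by least squares on a
  coarse grid of survival-factor pairs) and polished by
  Levenberg–Marquardt with `l ∈ (0, 1]`; components are reported in
  canonical order `l1 >= l2`.
* The QC rule — reject a cell when a single-frame drop exceeds 5× its
  median absolute successive difference — quantifies an otherwise
  qualitative "sudden drop" criterion. The multiple is exposed in the
  configuration and `Inf` disables the filter; it is a stand-in, not a
  measured threshold.

## Numerical choices and degenerate inputs

* Pairs with non-positive variance estimates are skipped (logged, not
  errors); negative pairwise estimates are excluded from the KDE but
  counted in diagnostics.
* Mode extraction: Gaussian KDE in $\log_{10}$ space, Silverman
  bandwidth, 512-point grid over the sample range; at least 30 positive
  estimates are required.
* Kernel matrices get a $10^{-8}\theta_0$ jitter only if the Cholesky
  fails; covariance updates use the Joseph-stabilized form and are
  re-symmetrized.
* Posterior-number densities are normalized on their grids to $10^{-6}$;
  the single-measurement posterior keeps negative-count support (the
  noise model allows it) and reports the mass below zero.
* Replicate combination interprets the kernel as log-normal with
  $\sigma_K^2 = 10^{-2}$ — a normal in log space, the only reading
  consistent with strictly positive parameters — and samples the pooled
  target by adaptive log-space random-walk Metropolis. Working with
  densities *over the parameters* while proposing in log coordinates
  requires the $+\sum\log\theta$ Jacobian in the target; its omission
  is a subtle bug that biases every combined posterior low by
  $O(\sigma^2)$, which the product-of-Gaussians oracle test guards.

## Problem sizes

The test and acceptance runs use: 150-cell cohorts of 45 frames for the
order-of-magnitude checks; 1000 replicate ensembles of $10^4$ molecules
per cell of the bias-law grid; 50 random instances for the filter
oracle; and 100 repetitions of 3-cell inference (6 chains × 1400
sweeps) for the calibration check — sizes chosen to make the Monte
Carlo error comfortably smaller than each check's tolerance.

## Known limitations

* The estimator degrades when bleaching completes well before the end of
  the experiment (late frames carry no signal and corrupt the GP mean)
  and at very low counts, where the Gaussian approximations behind both
  routes thin out.
* With few cells and realistic noise the Bayesian route's posterior for
  $\nu$ can be genuinely multimodal (see above); treat small-cohort
  credible intervals with care.
* The mono-exponential estimator used for comparison in the source
  literature is out of scope here, as is everything upstream of
  corrected traces (segmentation, registration, acquisition).
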