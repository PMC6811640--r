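# bleachcount

Absolute protein numbers from photobleaching fluctuation analysis.

Fluorescence microscopes report signal in arbitrary camera units; most
quantitative questions need numbers of molecules. `bleachcount` converts
single-cell photobleaching time series into absolute counts by exploiting
that the *fluctuations* of a bleaching trace scale with the number of
molecules behind it, not with their concentration: for fluorescence
`Y = nu * X` (brightness per molecule `nu`, count `X`),
`Var[Y] ∝ nu * E[Y]`, so at the same brightness a noisy decay means few
bright molecules and a smooth one means many dim molecules. It is aimed
at anyone doing quantitative wide-field fluorescence microscopy — the
only experiment required is bleaching fixed cells under sustained
illumination, plus matched non-fluorescent (wild-type) cells.

## The estimator

Stochastic first-order bleaching of `x0` molecules leaves a binomial
count with `E[X_t] = x0 * l` and `Var[X_t] = x0 * l * (1 - l)` for
survival probability `l = exp(-lambda * t)`. Eliminating `l` gives, in
fluorescence units, the closed-form estimator

    xhat0 = E[Y_t] * (y0 - E[Y_t]) / Var[Y_t]

valid at every positive time and independent of the (possibly
multi-exponential, heterogeneous) bleaching details. Per cell, `E[Y_t]`
comes from Gaussian-process smoothing and `Var[Y_t]` from squared
residuals; every positive-time frame yields one estimate, all estimates
from all cells are pooled, and the mode of the kernel density over
`log10(xhat0)` is the answer.

The package also implements the model-explicit Bayesian alternative the
estimator is benchmarked against — a two-pool linear-noise bleaching
model, a Kalman-filter likelihood with measurement noise whose variance
is quadratic in the signal, and Metropolis-within-Gibbs sampling with
adaptive parallel tempering — together with posterior conversion of
fluorescence into molecule-number distributions, replicate combination,
and an exact stochastic simulator that provides ground truth for every
stage. The methods vignette
(`vignettes/photobleaching-fluctuation-analysis.Rmd`) documents the
models, defaults and numerical choices.

## Worked example

Simulate a cohort with known truth and recover the count:

```r
library(bleachcount)

sim <- simulate_cohort(40, hyper = default_cell_hyper(x0 = 1e4), seed = 7)
res <- estimate_numbers(sim$traces, seed = 7)
res$pooled
#> pooled fluctuation estimate: mode = 2.773e+04 molecules
#>   1144 estimates (1144 positive, 0 non-positive, 0 dropped)
```

The cohort bleaches 10,000 molecules per cell (two pools, cell-to-cell
rate variation, realistic camera noise at brightness 20); the pooled
mode of 2.8e4 lands within the order of magnitude of the truth, the
claim this method makes — with this noise level the residual
overestimation comes from the smoother slightly chasing fluctuations,
a bias direction the vignette discusses. Each of the 26 cells surviving
quality control contributes 44 pairwise estimates (`res$cells` holds
per-cell GP hyperparameters, `res$qc` the rejection log).

A reference sanity check, converting a published cytoplasmic
concentration of 180 nM (nucleus 3x higher; volumes 39 + 3 fl) into a
count:

```r
sum(molecules_from_concentration(c(180, 540), c(39, 3)))
#> [1] 5203.13
```

The same workflows are scriptable from a shell:

```sh
Rscript inst/cli/bleachcount.R simulate --cells 40 --seed 7 --out traces.csv
Rscript inst/cli/bleachcount.R estimate --traces traces.csv --out estimate.json
Rscript inst/cli/bleachcount.R infer    --traces traces.csv --out samples.csv
```

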