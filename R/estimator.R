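# The fluctuation estimator: pairwise estimates of the initial molecule
# number from (y0, y_t) pairs, pooling across cells and times, mode
# extraction, and the bias/accuracy theory for heterogeneous molecules.

#' Pairwise fluctuation estimate of the initial molecule number
#'
#' For stochastic first-order bleaching the count variance satisfies
#' `Var[X_t] = E[X_t] (x0 - E[X_t]) / x0`; multiplying by the squared
#' brightness and solving for `x0` gives the estimator
#' `xhat0 = E[Y_t] * (y0 - E[Y_t]) / Var[Y_t]`, valid at every positive
#' time. Negative values (possible when `E[Y_t] > y0`) are returned as-is
#' so callers can count them; pooling later drops them.
#'
#' @param y0 Fluorescence at `t = 0` (camera units).
#' @param mean_t Estimated `E[Y_t]` (vectorized).
#' @param var_t Estimated `Var[Y_t]` (vectorized, must be `> 0`).
#'
#' @return Estimated initial molecule count(s); `NA` where `var_t <= 0`.
#' @export
#' @examples
#' pair_estimate(100, 50, 25)  # 100
pair_estimate <- function(y0, mean_t, var_t) {
  out <- mean_t * (y0 - mean_t) / var_t
  out[!is.finite(var_t) | var_t <= 0] <- NA_real_
  out
}

#' All pairwise estimates for one cell
#'
#' Applies [pair_estimate()] to every positive-time point of a smoothed
#' trace, producing `n_d - 1` estimates for an `n_d`-point trace. By
#' default `y0` is the GP posterior mean at `t = 0` rather than the raw
#' first frame, so the first frame's own measurement noise is not injected
#' into every pair; set `y0_convention = "raw"` to use the raw frame.
#'
#' @param values Raw fluorescence values of the cell.
#' @param smoothed A `smoothed_trace` from [smooth_trace()].
#' @param cell_id Identifier carried into the output.
#' @param y0_convention `"smoothed"` (default) or `"raw"`.
#' @param drop_first Number of leading time points to exclude entirely
#'   (default 0; the Bayesian workflow conventionally drops 5).
#'
#' @return data.frame with columns `cell_id`, `t`, `xhat0`; zero rows if
#'   the smoothing was degenerate.
#' @export
estimate_cell <- function(values, smoothed, cell_id = "cell",
                          y0_convention = c("smoothed", "raw"),
                          drop_first = 0) {
  y0_convention <- match.arg(y0_convention)
  if (is.null(smoothed$mean)) {
    return(data.frame(cell_id = character(), t = numeric(),
                      xhat0 = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(length(values) == length(smoothed$mean))
  y0 <- if (y0_convention == "smoothed") smoothed$mean[1] else values[1]
  keep <- seq_along(smoothed$times) > max(1, drop_first)
  keep <- keep & smoothed$times > 0
  xhat <- pair_estimate(y0, smoothed$mean[keep], smoothed$var[keep])
  data.frame(cell_id = cell_id, t = smoothed$times[keep], xhat0 = xhat,
             stringsAsFactors = FALSE)
}

#' Pool pairwise estimates and extract the mode
#'
#' Pools the positive pairwise estimates from all cells, forms a Gaussian
#' kernel density estimate over `log10(xhat0)` (Silverman bandwidth,
#' 512-point grid spanning the sample), and reports the argmax as the point
#' estimate. Non-positive and non-finite estimates are excluded from the
#' density but counted in the diagnostics.
#'
#' @param estimates Numeric vector (or data.frame from [estimate_cell()]
#'   with an `xhat0` column) of pairwise estimates.
#' @param min_estimates Minimum number of positive estimates required
#'   (default 30).
#' @param grid_n KDE grid size (default 512).
#'
#' @return A list of class `pooled_estimate`: `mode`, `n_total`,
#'   `n_positive`, `n_negative`, `n_dropped`, `kde` (data.frame
#'   `log10_x`, `density`).
#' @export
pool_and_mode <- function(estimates, min_estimates = 30, grid_n = 512) {
  x <- if (is.data.frame(estimates)) estimates$xhat0 else
    as.numeric(estimates)
  n_total <- length(x)
  finite <- x[is.finite(x)]
  pos <- finite[finite > 0]
  if (length(pos) < min_estimates) {
    stop("too few positive pairwise estimates to pool (",
         length(pos), " < ", min_estimates, ")")
  }
  lx <- log10(pos)
  if (stats::sd(lx) == 0) {
    mode <- pos[1]
    kde <- data.frame(log10_x = lx[1], density = Inf)
  } else {
    d <- stats::density(lx, bw = "nrd0", n = grid_n,
                        from = min(lx), to = max(lx))
    mode <- 10^d$x[which.max(d$y)]
    kde <- data.frame(log10_x = d$x, density = d$y)
  }
  structure(
    list(mode = mode, n_total = n_total, n_positive = length(pos),
         n_negative = sum(finite <= 0), n_dropped = n_total -
           length(finite), kde = kde),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled fluctuation estimate: mode = %.4g molecules\n  %d estimates (%d positive, %d non-positive, %d dropped)\n",
    x$mode, x$n_total, x$n_positive, x$n_negative, x$n_dropped))
  invisible(x)
}

#' Full estimator pipeline on a cohort of traces
#'
#' Optionally corrects for autofluorescence, quality-filters, smooths each
#' cell with a GP, computes all pairwise estimates, and pools them.
#'
#' @param traces Long-format data.frame (`cell_id`, `time_s`,
#'   `fluorescence`).
#' @param wildtype Optional wild-type traces for autofluorescence
#'   correction.
#' @param config An [estimator_config()] list.
#' @param seed Integer seed controlling GP restart draws.
#'
#' @return A list: `pooled` ([pool_and_mode()] result), `estimates`
#'   (per-pair data.frame), `qc` (rejection log), `cells` (per-cell
#'   summaries with GP hyperparameters).
#' @export
estimate_numbers <- function(traces, wildtype = NULL,
                             config = estimator_config(), seed = 1) {
  check_trace_frame(traces)
  if (!is.null(wildtype)) {
    traces <- autofluorescence_correct(traces, wildtype)
  }
  qc <- qc_filter(traces, threshold = config$qc_threshold)
  ids <- unique(qc$kept$cell_id)
  if (length(ids) == 0) stop("all cells rejected by quality filtering")
  est <- vector("list", length(ids))
  cells <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- qc$kept[qc$kept$cell_id == ids[k], ]
    tr <- tr[order(tr$time_s), ]
    sm <- smooth_trace(tr$time_s, tr$fluorescence,
                       bounds = config$gp_bounds,
                       restarts = config$gp_restarts,
                       seed = seed + 7000L + k)
    est[[k]] <- estimate_cell(tr$fluorescence, sm, cell_id = ids[k],
                              y0_convention = config$y0_convention,
                              drop_first = config$drop_first)
    cells[[k]] <- data.frame(
      cell_id = ids[k],
      theta0 = sm$fit$theta0, theta1 = sm$fit$theta1,
      theta2 = sm$fit$theta2, gp_converged = sm$fit$converged,
      n_pairs = nrow(est[[k]]), stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, est)
  pooled <- pool_and_mode(estimates,
                          min_estimates = config$min_estimates,
                          grid_n = config$kde_grid_n)
  list(pooled = pooled, estimates = estimates, qc = qc$rejections,
       cells = do.call(rbind, cells))
}

#' Options for the fluctuation-estimator pipeline
#'
#' @param y0_convention `"smoothed"` (default) or `"raw"` first-frame
#'   fluorescence.
#' @param drop_first Leading time points to exclude (default 0).
#' @param qc_threshold Sudden-drop rejection multiple (default 5).
#' @param gp_bounds GP hyperparameter bounds; `NULL` means [gp_bounds()]
#'   defaults.
#' @param gp_restarts GP optimizer restarts (default 5).
#' @param min_estimates Minimum positive estimates to pool (default 30).
#' @param kde_grid_n KDE grid size (default 512).
#'
#' @return Named list of options.
#' @export
estimator_config <- function(y0_convention = "smoothed", drop_first = 0,
                             qc_threshold = 5, gp_bounds = NULL,
                             gp_restarts = 5, min_estimates = 30,
                             kde_grid_n = 512) {
  if (is.null(gp_bounds)) {
    gp_bounds <- get("gp_bounds", envir = parent.env(environment()))()
  }
  list(y0_convention = y0_convention, drop_first = drop_first,
       qc_threshold = qc_threshold, gp_bounds = gp_bounds,
       gp_restarts = gp_restarts, min_estimates = min_estimates,
       kde_grid_n = kde_grid_n)
}

#' Moment inputs for the heterogeneous-molecule bias theory
#'
#' Collects the joint moments of the per-molecule brightness `nu` and
#' survival probability `l` distribution, the measurement-noise variance,
#' and the true count, as needed by [predicted_bias()] and
#' [accuracy_margins()].
#'
#' @param E_nu,Var_nu Mean and variance of brightness.
#' @param E_ell,Var_ell Mean and variance of survival probability.
#' @param E_nul,Var_nul Mean and variance of the product `nu * l`.
#' @param Cov_nu_nul Covariance of `nu` and `nu * l`.
#' @param sigma_e2 Measurement-noise variance (camera units squared).
#' @param x0 True initial molecule count.
#'
#' @return A list of class `bias_inputs`.
#' @export
bias_inputs <- function(E_nu, Var_nu, E_ell, Var_ell, E_nul, Var_nul,
                        Cov_nu_nul, sigma_e2, x0) {
  stopifnot(E_nu > 0, Var_nu >= 0, Var_ell >= 0, Var_nul >= 0,
            E_ell > 0, E_ell < 1, sigma_e2 >= 0, x0 > 0)
  structure(
    list(E_nu = E_nu, Var_nu = Var_nu, E_ell = E_ell, Var_ell = Var_ell,
         E_nul = E_nul, Var_nul = Var_nul, Cov_nu_nul = Cov_nu_nul,
         sigma_e2 = sigma_e2, x0 = x0),
    class = "bias_inputs"
  )
}

#' Predicted relative bias of the fluctuation estimator
#'
#' Under molecule-level heterogeneity with measurement noise, the expected
#' estimate is `x0 / (1 + eps)` with
#' `eps = (sigma_e^2 / x0 + Cov[nu, nu l] - Var[nu l]) /
#'        (E[nu l] (E[nu] - E[nu l]))`.
#' Positive `eps` (noise-dominated) means underestimation; negative `eps`
#' (heterogeneity-dominated with small noise) means overestimation.
#'
#' @param b A [bias_inputs()] object.
#'
#' @return A list: `epsilon` and `expected_xhat0 = x0 / (1 + epsilon)`.
#' @export
predicted_bias <- function(b) {
  stopifnot(inherits(b, "bias_inputs"))
  denom <- b$E_nul * (b$E_nu - b$E_nul)
  if (abs(denom) < .Machine$double.eps) {
    stop("bias undefined: E[nu] equals E[nu l] (no bleaching)")
  }
  eps <- (b$sigma_e2 / b$x0 + b$Cov_nu_nul - b$Var_nul) / denom
  list(epsilon = eps, expected_xhat0 = b$x0 / (1 + eps))
}

#' Accuracy margins of the fluctuation estimator
#'
#' Evaluates both sides of the three accuracy conditions: the general
#' condition `|sigma_e^2/x0 + Cov[nu, nu l] - Var[nu l]| <<
#' E[nu l](E[nu] - E[nu l])`; its homogeneous-brightness specialization
#' `sigma_e^2/(E[nu]^2 x0) << E[l] - E[l]^2 + Var[l]`; and the
#' homogeneous-survival specialization whose right-hand side carries the
#' factor `(1 - Var[nu]/E[nu]^2)` and so fails outright when brightness
#' variation exceeds its squared mean.
#'
#' @param b A [bias_inputs()] object.
#'
#' @return A list of three elements (`general`, `homogeneous_nu`,
#'   `homogeneous_ell`), each with `lhs`, `rhs`, and `ratio = lhs/rhs`.
#' @export
accuracy_margins <- function(b) {
  stopifnot(inherits(b, "bias_inputs"))
  lhs_gen <- abs(b$sigma_e2 / b$x0 + b$Cov_nu_nul - b$Var_nul)
  rhs_gen <- b$E_nul * (b$E_nu - b$E_nul)
  lhs_spec <- b$sigma_e2 / (b$E_nu^2 * b$x0)
  rhs_nu <- b$E_ell - b$E_ell^2 + b$Var_ell
  rhs_ell <- (b$E_ell - b$E_ell^2) * (1 - b$Var_nu / b$E_nu^2)
  ratio <- function(l, r) if (r != 0) l / r else Inf
  list(
    general = list(lhs = lhs_gen, rhs = rhs_gen,
                   ratio = ratio(lhs_gen, rhs_gen)),
    homogeneous_nu = list(lhs = lhs_spec, rhs = rhs_nu,
                          ratio = ratio(lhs_spec, rhs_nu)),
    homogeneous_ell = list(lhs = lhs_spec, rhs = rhs_ell,
                           ratio = ratio(lhs_spec, rhs_ell))
  )
}

#' Molecule count from a molar concentration and compartment volume
#'
#' `count = concentration * volume * N_A`, with the concentration in
#' nanomolar and the volume in femtoliters (the natural units for single
#' yeast cells). Vectorized; sum over compartments for a whole-cell count.
#'
#' @param conc_nM Concentration(s) in nM.
#' @param volume_fl Volume(s) in fl.
#'
#' @return Molecule count(s).
#' @export
#' @examples
#' # cytoplasm at 180 nM in 39 fl plus a 3-fl nucleus at 540 nM
#' sum(molecules_from_concentration(c(180, 540), c(39, 3)))  # ~5200
molecules_from_concentration <- function(conc_nM, volume_fl) {
  stopifnot(all(conc_nM >= 0), all(volume_fl >= 0))
  avogadro <- 6.02214076e23
  conc_nM * 1e-9 * volume_fl * 1e-15 * avogadro
}

#' Steady-state mature (fluorescent) fraction of a tagged protein
#'
#' With maturation time `tau_m` and effective dilution by growth with
#' doubling time `tau_d`, the steady-state fraction of tagged protein that
#' has matured (and so fluoresces) is
#' `(1/tau_m) / (1/tau_m + 1/tau_d)`. This bounds how much of the true
#' protein count fluorescence-based estimates can see.
#'
#' @param maturation_time_min Maturation time (minutes).
#' @param doubling_time_min Doubling time (minutes).
#'
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' mature_fraction(45, 100)  # ~0.69
mature_fraction <- function(maturation_time_min, doubling_time_min) {
  stopifnot(maturation_time_min > 0, doubling_time_min > 0)
  km <- 1 / maturation_time_min
  kd <- 1 / doubling_time_min
  km / (km + kd)
}

#' Likelihood profile for the initial count from one measurement pair
#'
#' Independent check that the pairwise estimator is a maximum-likelihood
#' estimate. For noiseless data summarized by (`y0`, `mu_y = E[Y]`,
#' `var_y = Var[Y]`), the likelihood of `x0` is a chain of change-of-
#' variable delta functions over the unobserved brightness, survival
#' probability and latent moments. Here each delta is smoothed to a narrow
#' Gaussian of relative width `rel_width`; the delta fixing `y0 = nu x0`
#' is evaluated exactly, and the remaining integral over the survival
#' probability is done in closed form (a Gaussian convolution). As
#' `rel_width -> 0` the profile's peak converges to the estimator value.
#'
#' @param x0 Candidate value(s) of the initial count.
#' @param y0 Initial fluorescence.
#' @param mu_y Mean fluorescence at the paired time.
#' @param var_y Fluorescence variance at the paired time.
#' @param rel_width Relative width of the smoothed delta functions
#'   (default `1e-6`).
#'
#' @return Log-likelihood values (unnormalized), same length as `x0`.
#' @export
x0_loglik_profile <- function(x0, y0, mu_y, var_y, rel_width = 1e-6) {
  stopifnot(y0 > 0, mu_y > 0, mu_y < y0, var_y > 0)
  nu <- y0 / x0
  # smoothed delta widths, scaled to the magnitude of each argument
  eps1 <- rel_width * (var_y / nu^2)   # variance-matching delta
  eps2 <- rel_width * (mu_y / nu)      # mean-matching delta
  B <- mu_y / nu
  A <- var_y / nu^2 - mu_y / nu
  m1 <- -A / B
  m2 <- mu_y / (nu * x0)
  s2 <- (eps1 / B)^2 + (eps2 / x0)^2
  # log of: (x0 / y0^3) * (1/x0) * (1 / (B * x0)) * N(m1 - m2; 0, s2),
  # the delta over nu contributing 1/x0 and the prior over nu a constant
  -log(x0) - 3 * log(nu) - log(B) - log(x0) +
    stats::dnorm(m1 - m2, 0, sqrt(s2), log = TRUE)
}

#' Maximum-likelihood initial count from one measurement pair
#'
#' Numerically maximizes [x0_loglik_profile()] over `x0`; agrees with
#' [pair_estimate()] to high relative accuracy, verifying the estimator's
#' maximum-likelihood property on a worked instance.
#'
#' @inheritParams x0_loglik_profile
#' @param interval Search interval for `x0` (default spans eight decades
#'   around `mu_y * (y0 - mu_y) / var_y`).
#'
#' @return The maximizing `x0`.
#' @export
mle_x0 <- function(y0, mu_y, var_y, rel_width = 1e-6, interval = NULL) {
  guess <- mu_y * (y0 - mu_y) / var_y
  if (is.null(interval)) interval <- c(guess * 1e-4, guess * 1e4)
  opt <- stats::optimize(
    function(x) x0_loglik_profile(x, y0, mu_y, var_y, rel_width),
    interval = interval, maximum = TRUE,
    tol = .Machine$double.eps^0.5 * guess
  )
  opt$maximum
}
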