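# Gaussian-process smoothing of bleaching traces with a squared-exponential
# kernel: k(t, t') = theta0 * exp(-theta1 * (t - t')^2 / 2), plus i.i.d.
# observation noise theta2 on the diagonal. Hyperparameters are found by
# maximizing the marginal likelihood inside hard box bounds. No installed
# package exposes this bounded marginal-likelihood surface directly, so the
# (small, dense) GP algebra is done here with Cholesky factorizations.

#' Hyperparameter box bounds for trace smoothing
#'
#' Hard prior bounds on the squared-exponential GP hyperparameters:
#' `theta0` (signal variance), `theta1` (inverse squared length scale), and
#' `theta2` (observation noise variance). The defaults deliberately bracket
#' camera-unit fluorescence scales from hundreds to tens of millions.
#'
#' @param theta0 Length-2 bounds for the signal variance.
#' @param theta1 Length-2 bounds for the inverse squared length scale.
#' @param theta2 Length-2 bounds for the noise variance.
#'
#' @return Named list of bound pairs.
#' @export
gp_bounds <- function(theta0 = c(1e3, 1e14),
                      theta1 = c(1e-8, 1),
                      theta2 = c(10, 1e10)) {
  stopifnot(theta0[1] < theta0[2], theta1[1] < theta1[2],
            theta2[1] < theta2[2], theta0[1] > 0, theta1[1] > 0,
            theta2[1] > 0)
  list(theta0 = theta0, theta1 = theta1, theta2 = theta2)
}

# Negative log marginal likelihood in log-hyperparameter space.
gp_nlml <- function(log_theta, times, y_centered) {
  th <- exp(log_theta)
  n <- length(y_centered)
  D2 <- outer(times, times, "-")^2
  K <- th[1] * exp(-th[2] * D2 / 2)
  Ky <- K + diag(th[3], n)
  ch <- tryCatch(chol(Ky), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(Ky + diag(1e-8 * th[1], n)),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e12)
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), y_centered))
  as.numeric(0.5 * sum(y_centered * alpha) + sum(log(diag(ch))) +
               0.5 * n * log(2 * pi))
}

#' Fit GP hyperparameters to one trace
#'
#' Maximizes the GP log marginal likelihood over the three hyperparameters
#' in log space with `L-BFGS-B` inside the box bounds, using one
#' data-driven start plus `restarts` starts drawn uniformly in the log of
#' each bound interval. The trace is mean-centered before fitting (the GP
#' prior mean is zero); the offset is restored at prediction time.
#'
#' @param times Sample times (seconds); at least 10 points.
#' @param values Fluorescence values.
#' @param bounds Box bounds from [gp_bounds()].
#' @param restarts Number of random restarts (default 5).
#' @param seed Optional integer seed for the restart draws.
#'
#' @return A list of class `gp_fit`: `theta0`, `theta1`, `theta2`,
#'   `log_marginal`, `offset`, `converged`, `n_restarts`.
#' @export
fit_gp <- function(times, values, bounds = gp_bounds(), restarts = 5,
                   seed = NULL) {
  times <- as.numeric(times)
  y <- as.numeric(values)
  stopifnot(length(times) == length(y))
  if (length(y) < 10) stop("need at least 10 time points for GP smoothing")
  if (!is.null(seed)) set.seed(seed)
  offset <- mean(y)
  yc <- y - offset

  lo <- log(c(bounds$theta0[1], bounds$theta1[1], bounds$theta2[1]))
  hi <- log(c(bounds$theta0[2], bounds$theta1[2], bounds$theta2[2]))
  clip <- function(v) pmin(pmax(v, lo), hi)

  span <- diff(range(times))
  start0 <- clip(log(c(
    max(stats::var(yc), 1),
    1 / max((span / 5)^2, 1e-12),
    max(stats::var(diff(yc)) / 2, 1)
  )))
  starts <- list(start0)
  for (r in seq_len(restarts)) {
    starts <- c(starts, list(stats::runif(3, lo, hi)))
  }

  best <- NULL
  n_ok <- 0
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_nlml, method = "L-BFGS-B", lower = lo, upper = hi,
                   times = times, y_centered = yc,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_ok <- n_ok + 1
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(
      list(theta0 = NA_real_, theta1 = NA_real_, theta2 = NA_real_,
           log_marginal = NA_real_, offset = offset, converged = FALSE,
           n_restarts = length(starts)),
      class = "gp_fit"))
  }
  th <- exp(clip(best$par))
  structure(
    list(theta0 = th[1], theta1 = th[2], theta2 = th[3],
         log_marginal = -best$value, offset = offset, converged = TRUE,
         n_restarts = length(starts)),
    class = "gp_fit"
  )
}

#' GP posterior mean at the observed times
#'
#' Standard GP regression posterior mean, treating `theta2` as i.i.d.
#' observation noise and evaluating only at the training inputs (the
#' fluctuation-variance rule is applied only at observed times, so no
#' extrapolation is needed).
#'
#' @param times Sample times.
#' @param values Fluorescence values.
#' @param fit A `gp_fit` object.
#'
#' @return Numeric vector: the smoothed mean `E[Y_t]` at each input time.
#' @export
predict_mean <- function(times, values, fit) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!isTRUE(fit$converged)) stop("GP fit did not converge for this cell")
  times <- as.numeric(times)
  yc <- as.numeric(values) - fit$offset
  n <- length(yc)
  D2 <- outer(times, times, "-")^2
  K <- fit$theta0 * exp(-fit$theta1 * D2 / 2)
  Ky <- K + diag(fit$theta2, n)
  ch <- tryCatch(chol(Ky), error = function(e)
    chol(Ky + diag(1e-8 * fit$theta0, n)))
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  as.numeric(K %*% alpha) + fit$offset
}

#' Per-time fluctuation variance from squared residuals
#'
#' Estimates `Var[Y_t]` at each time as the squared residual
#' `(y_t - E[Y_t])^2` about the smoothed mean. A single squared residual is
#' a noisy but unbiased-in-aggregate variance estimate; pooling across many
#' cells and times is what stabilizes the downstream estimator.
#'
#' @param values Observed fluorescence.
#' @param mean Smoothed mean of the same length.
#'
#' @return Numeric vector of squared residuals (zeros allowed).
#' @export
residual_variance <- function(values, mean) {
  stopifnot(length(values) == length(mean))
  (as.numeric(values) - as.numeric(mean))^2
}

#' Smooth one trace and derive fluctuation variances
#'
#' Convenience wrapper: fits GP hyperparameters, computes the posterior
#' mean, and attaches squared-residual variance estimates.
#'
#' @inheritParams fit_gp
#'
#' @return A list of class `smoothed_trace`: `times`, `mean`, `var`,
#'   `fit`.
#' @export
smooth_trace <- function(times, values, bounds = gp_bounds(), restarts = 5,
                         seed = NULL) {
  fit <- fit_gp(times, values, bounds = bounds, restarts = restarts,
                seed = seed)
  if (!isTRUE(fit$converged)) {
    return(structure(list(times = times, mean = NULL, var = NULL,
                          fit = fit), class = "smoothed_trace"))
  }
  m <- predict_mean(times, values, fit)
  structure(
    list(times = as.numeric(times), mean = m,
         var = residual_variance(values, m), fit = fit),
    class = "smoothed_trace"
  )
}
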