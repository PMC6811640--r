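# Convert posterior parameter samples into posterior distributions over
# molecule numbers: for a single fluorescence value, for a population
# mean, and across experimental replicates.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                         utils::tail(y, -1)) / 2)

new_number_posterior <- function(grid, density, mass_below_zero = 0) {
  z <- trapz(grid, density)
  density <- density / z
  cum <- cumsum(c(0, diff(grid) * (utils::head(density, -1) +
                                     utils::tail(density, -1)) / 2))
  mode <- grid[which.max(density)]
  ci <- c(grid[which.min(abs(cum - 0.025))],
          grid[which.min(abs(cum - 0.975))])
  structure(
    list(grid = grid, density = density, mode = mode, ci95 = ci,
         mass_below_zero = mass_below_zero),
    class = "number_posterior"
  )
}

#' @export
print.number_posterior <- function(x, ...) {
  cat(sprintf(
    "number_posterior: mode %.4g, 95%% interval [%.4g, %.4g]\n",
    x$mode, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Posterior over the molecule number behind one fluorescence value
#'
#' Marginalizes the single-measurement conversion over the parameter
#' posterior: for each sample, `x | y, theta` is normal with mean
#' `(y - f) / nu` and variance
#' `(sigma_e0^2 + y sigma_e1^2 + (y sigma_e2)^2) / nu^2`; the posterior is
#' the equally weighted mixture over samples, evaluated on a grid spanning
#' the mixture's +/- 6 sd range. Negative-x support is retained (the noise
#' model allows it) and the mass below zero is reported.
#'
#' @param y Fluorescence value (camera units).
#' @param samples data.frame of posterior draws with columns `nu`,
#'   `sigma_e0`, `sigma_e1`, `sigma_e2` and optionally `f` (default 0).
#' @param grid_n Grid resolution (default 1024).
#'
#' @return A `number_posterior` object: `grid`, normalized `density`,
#'   `mode`, `ci95`, `mass_below_zero`.
#' @export
number_posterior_single <- function(y, samples, grid_n = 1024) {
  stopifnot(is.finite(y), nrow(samples) >= 1)
  f <- if ("f" %in% names(samples)) samples$f else 0
  nu <- samples$nu
  means <- (y - f) / nu
  vars <- (samples$sigma_e0^2 + y * samples$sigma_e1^2 +
             (y * samples$sigma_e2)^2) / nu^2
  sds <- sqrt(pmax(vars, 0))
  sd_floor <- max(max(abs(means)) * 1e-9, 1e-12)
  sds <- pmax(sds, sd_floor)
  lo <- min(means - 6 * sds)
  hi <- max(means + 6 * sds)
  grid <- seq(lo, hi, length.out = grid_n)
  dens <- rowMeans(vapply(seq_along(means), function(k)
    stats::dnorm(grid, means[k], sds[k]), numeric(grid_n)))
  below <- if (lo < 0) {
    mean(stats::pnorm(0, means, sds))
  } else 0
  new_number_posterior(grid, dens, mass_below_zero = below)
}

#' Posterior over the population-mean molecule number
#'
#' For the mean fluorescence of `N` cells the per-sample conversion
#' concentrates on `ybar / nu` (the measurement variance shrinks as `1/N`
#' and the mean offset is assumed small relative to `ybar`), so the
#' posterior is represented as a kernel-smoothed mixture of `ybar / nu`
#' over the brightness samples, with a log-normal kernel of log-scale
#' standard deviation `sigma_K` (default 0.1, i.e. kernel variance 1e-2).
#'
#' @param mean_y Mean fluorescence over cells (camera units).
#' @param mean_f Mean residual offset (reported in the delta-validity
#'   check; not used in the delta-limit density).
#' @param N Number of cells averaged.
#' @param samples data.frame of posterior draws with column `nu`.
#' @param sigma_K Log-normal kernel standard deviation (log scale).
#' @param grid_n Grid resolution.
#'
#' @return A `number_posterior` object (grid over positive `xbar`), with
#'   an added `delta_ok` flag for the validity of the delta approximation.
#' @export
population_mean_posterior <- function(mean_y, mean_f = 0, N = 1, samples,
                                      sigma_K = 0.1, grid_n = 1024) {
  stopifnot(N >= 1, mean_y > 0, nrow(samples) >= 1)
  centers <- mean_y / samples$nu
  lo <- min(centers) * exp(-6 * sigma_K)
  hi <- max(centers) * exp(6 * sigma_K)
  grid <- exp(seq(log(lo), log(hi), length.out = grid_n))
  dens <- rowMeans(vapply(seq_along(centers), function(k)
    stats::dlnorm(grid, log(centers[k]), sigma_K), numeric(grid_n)))
  out <- new_number_posterior(grid, dens)
  out$delta_ok <- abs(mean_f) < 0.1 * mean_y
  out
}

#' Combine posterior samples from independent replicates
#'
#' Conditional independence of replicates given the parameters means the
#' combined posterior is the product of the per-replicate posteriors
#' divided by the prior to the power `N - 1`. Each per-replicate posterior
#' is represented by a kernel density estimate over its samples with
#' isotropic log-normal kernels (variance `sigma_K^2`), and the combined
#' target is sampled with a log-space random-walk Metropolis algorithm
#' whose scale adapts toward 0.44 acceptance.
#'
#' @param sample_sets List of data.frames of posterior draws over the same
#'   (positive) parameters.
#' @param spec A [prior_spec()]; only parameters present in the samples
#'   are used.
#' @param sigma_K Kernel standard deviation on the log scale (default
#'   0.1).
#' @param n_out Number of combined draws to return.
#' @param n_kde Per-replicate samples retained for the KDE (thinned if
#'   larger).
#' @param thin Random-walk steps per retained draw (default 5), which
#'   keeps the returned draws close to independent.
#' @param seed Integer seed.
#'
#' @return data.frame of combined posterior draws.
#' @export
combine_replicates <- function(sample_sets, spec = prior_spec(),
                               sigma_K = 0.1, n_out = 2000, n_kde = 500,
                               thin = 5, seed = 1) {
  stopifnot(length(sample_sets) >= 1)
  set.seed(as.integer(seed))
  pars <- Reduce(intersect, lapply(sample_sets, names))
  pars <- setdiff(pars, "loglik")
  if (length(pars) == 0) stop("sample sets share no parameters")
  N <- length(sample_sets)

  logs <- lapply(sample_sets, function(df) {
    m <- as.matrix(df[, pars, drop = FALSE])
    if (any(m <= 0)) stop("log-normal kernels require positive samples")
    lm <- log(m)
    if (nrow(lm) > n_kde) {
      lm <- lm[round(seq(1, nrow(lm), length.out = n_kde)), , drop = FALSE]
    }
    lm
  })

  log_kde <- function(lth, lm) {
    # isotropic log-normal KDE evaluated at log-point lth
    d2 <- colSums((t(lm) - lth)^2)
    m <- max(-d2 / (2 * sigma_K^2))
    # Jacobian terms (-sum(lth)) are common to every set; keep them so
    # the density is over theta, not log(theta)
    m + log(mean(exp(-d2 / (2 * sigma_K^2) - m))) -
      length(lth) * log(sigma_K * sqrt(2 * pi)) - sum(lth)
  }

  log_target <- function(lth) {
    lk <- sum(vapply(logs, function(lm) log_kde(lth, lm), numeric(1)))
    if (!is.finite(lk)) return(-Inf)
    # + sum(lth): Jacobian of sampling theta through log coordinates
    lk <- lk + sum(lth)
    if (N > 1) {
      lp <- sum(vapply(seq_along(pars), function(i) {
        sp <- spec[[pars[i]]]
        if (is.null(sp)) 0 else log_prior_one(exp(lth[i]), sp)
      }, numeric(1)))
      if (!is.finite(lp)) return(-Inf)
      lk - (N - 1) * lp
    } else {
      lk
    }
  }

  lth <- colMeans(logs[[1]])
  lt_cur <- log_target(lth)
  if (!is.finite(lt_cur)) stop("replicate KDEs have no common support")
  scale <- sigma_K
  draws <- matrix(NA_real_, n_out, length(pars),
                  dimnames = list(NULL, pars))
  burn <- max(200, n_out %/% 4)
  total <- n_out * thin + burn
  acc <- 0
  for (it in seq_len(total)) {
    prop <- lth + stats::rnorm(length(lth), 0, scale)
    lt_prop <- log_target(prop)
    if (is.finite(lt_prop) &&
        log(stats::runif(1)) < lt_prop - lt_cur) {
      lth <- prop
      lt_cur <- lt_prop
      acc <- acc + 1
    }
    if (it <= burn) {
      scale <- min(max(scale * exp((1 / it^0.6) *
                                     ((acc / it) - 0.44)), 1e-3), 2)
    } else if ((it - burn) %% thin == 0) {
      draws[(it - burn) %/% thin, ] <- exp(lth)
    }
  }
  as.data.frame(draws)
}
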