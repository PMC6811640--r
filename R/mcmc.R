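# Posterior sampling over heterogeneous per-cell parameters
# (lambda1, lambda2, f, y0 = nu * x0, alpha) and homogeneous population
# parameters (nu, sigma_e0, sigma_e1, sigma_e2): proper bounded priors,
# nested-optimization initialization, Metropolis-within-Gibbs with
# adaptive parallel tempering.

#' Prior specification for the bleaching model
#'
#' Scale-free (1/x) priors for the homogeneous parameters and for the
#' per-cell initial fluorescence `y0 = nu * x0`; flat priors for the other
#' heterogeneous parameters. All priors are proper: every parameter is
#' boxed to a physically plausible range, and the defaults below are
#' deliberately broad (rates up to 1/s, brightness over six decades).
#'
#' @param lambda Bounds for both bleach rates (1/s).
#' @param f Bounds for the residual autofluorescence offset.
#' @param y0 Bounds for the per-cell initial fluorescence.
#' @param alpha Bounds for the pool-2 fraction.
#' @param nu Bounds for the brightness per molecule.
#' @param sigma_e0,sigma_e1,sigma_e2 Bounds for the noise scales.
#'
#' @return A list of class `prior_spec`; each element has `kind`
#'   (`"scale_free"` or `"flat"`) and `bounds`.
#' @export
prior_spec <- function(lambda = c(1e-6, 1),
                       f = c(-1e4, 1e4),
                       y0 = c(1, 1e12),
                       alpha = c(0, 1),
                       nu = c(1e-3, 1e3),
                       sigma_e0 = c(1, 1e4),
                       sigma_e1 = c(1e-3, 1e2),
                       sigma_e2 = c(1e-6, 1)) {
  mk <- function(kind, bounds) list(kind = kind, bounds = bounds)
  structure(list(
    lambda1 = mk("flat", lambda),
    lambda2 = mk("flat", lambda),
    f       = mk("flat", f),
    y0      = mk("scale_free", y0),
    alpha   = mk("flat", alpha),
    nu      = mk("scale_free", nu),
    sigma_e0 = mk("scale_free", sigma_e0),
    sigma_e1 = mk("scale_free", sigma_e1),
    sigma_e2 = mk("scale_free", sigma_e2)
  ), class = "prior_spec")
}

# Parameter containers -----------------------------------------------------
# theta: list(cells = n_r x 5 matrix [lambda1, lambda2, f, y0, alpha],
#             shared = named numeric [nu, sigma_e0, sigma_e1, sigma_e2])

cell_par_names <- c("lambda1", "lambda2", "f", "y0", "alpha")
shared_par_names <- c("nu", "sigma_e0", "sigma_e1", "sigma_e2")

make_theta <- function(cells, shared) {
  cells <- matrix(as.numeric(cells), ncol = 5,
                  dimnames = list(NULL, cell_par_names))
  shared <- stats::setNames(as.numeric(shared), shared_par_names)
  list(cells = cells, shared = shared)
}

log_prior_one <- function(value, spec1) {
  b <- spec1$bounds
  if (value < b[1] || value > b[2]) return(-Inf)
  if (spec1$kind == "scale_free") {
    -log(value) - log(log(b[2] / b[1]))
  } else {
    -log(b[2] - b[1])
  }
}

#' Log prior density of a parameter vector
#'
#' Sum of the per-parameter log priors: normalized `1/x` densities for
#' scale-free parameters, normalized uniform densities for flat ones, and
#' `-Inf` anywhere outside the bounds.
#'
#' @param theta List with `cells` (n_r x 5 matrix with columns `lambda1`,
#'   `lambda2`, `f`, `y0`, `alpha`) and `shared` (named vector `nu`,
#'   `sigma_e0`, `sigma_e1`, `sigma_e2`).
#' @param spec A [prior_spec()].
#'
#' @return Scalar log prior.
#' @export
log_prior <- function(theta, spec = prior_spec()) {
  lp <- 0
  for (nm in shared_par_names) {
    lp <- lp + log_prior_one(theta$shared[[nm]], spec[[nm]])
    if (!is.finite(lp)) return(-Inf)
  }
  for (j in seq_len(nrow(theta$cells))) {
    for (nm in cell_par_names) {
      lp <- lp + log_prior_one(theta$cells[j, nm], spec[[nm]])
      if (!is.finite(lp)) return(-Inf)
    }
  }
  unname(lp)
}

# Log likelihood of cell j under theta (compiled filter).
cell_loglik <- function(theta, j, data) {
  p <- theta$cells[j, ]
  s <- theta$shared
  x0 <- p[["y0"]] / s[["nu"]]
  kalman_loglik_cpp(data$values[[j]], data$times,
                    p[["lambda1"]], p[["lambda2"]],
                    x0 * (1 - p[["alpha"]]), x0 * p[["alpha"]],
                    p[["f"]], s[["nu"]], s[["sigma_e0"]],
                    s[["sigma_e1"]], s[["sigma_e2"]], TRUE)
}

all_cell_logliks <- function(theta, data) {
  vapply(seq_len(data$n_cells), function(j) cell_loglik(theta, j, data),
         numeric(1))
}

# Convert long traces to the internal per-cell list representation.
traces_to_data <- function(traces, drop_first = 0) {
  check_trace_frame(traces)
  ids <- unique(traces$cell_id)
  values <- list()
  times <- NULL
  for (k in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[k], ]
    tr <- tr[order(tr$time_s), ]
    if (drop_first > 0) tr <- tr[-seq_len(drop_first), , drop = FALSE]
    if (is.null(times)) times <- tr$time_s
    if (length(tr$time_s) != length(times) ||
        any(abs(tr$time_s - times) > 1e-9)) {
      stop("all cells must share one time grid for inference")
    }
    values[[k]] <- tr$fluorescence
  }
  list(values = values, times = times, ids = ids, n_cells = length(ids))
}

#' MCMC configuration
#'
#' @param n_chains Number of tempered chains (default 10).
#' @param iterations Post-initialization sweeps per chain.
#' @param burn_frac Fraction of sweeps treated as burn-in; adaptation of
#'   proposal scales and temperatures stops at the end of burn-in so the
#'   retained samples target the exact posterior.
#' @param thin Keep every `thin`-th cold-chain draw.
#' @param target_accept Metropolis acceptance target for the block
#'   proposals (default 0.234).
#' @param target_swap Adjacent-chain swap-rate target (default 0.234).
#' @param drop_first Leading frames to discard before filtering
#'   (default 0; large early-frame fluctuations sometimes warrant 5).
#' @param init_budget Function evaluations for the per-cell global
#'   optimization during initialization.
#' @param max_sweeps Coordinate-ascent sweeps during initialization.
#'
#' @return Named list of options.
#' @export
mcmc_config <- function(n_chains = 10, iterations = 2000,
                        burn_frac = 0.5, thin = 1,
                        target_accept = 0.234, target_swap = 0.234,
                        drop_first = 0, init_budget = 400,
                        max_sweeps = 4) {
  list(n_chains = n_chains, iterations = iterations,
       burn_frac = burn_frac, thin = thin,
       target_accept = target_accept, target_swap = target_swap,
       drop_first = drop_first, init_budget = init_budget,
       max_sweeps = max_sweeps)
}

# Initialization ------------------------------------------------------------

clip_to <- function(v, b) pmin(pmax(v, b[1]), b[2])

# Step-1 starting values from a bi-exponential fit of one trace, plus a
# quick closed-form fluctuation estimate of nu: the fitted curve serves
# as E[Y_t], the squared residuals as Var[Y_t], and the pairwise
# estimator's pooled median gives x0 and hence nu = amplitude / x0.
init_cell_from_biexp <- function(y, dt, spec) {
  n <- length(y)
  i <- seq_len(n) - 1
  fit <- tryCatch(fit_biexponential(y), error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) {
    tot <- max(y[1] - min(y), 1)
    return(list(cell = c(lambda1 = 0.003, lambda2 = 0.02, f = min(y),
                         y0 = tot, alpha = 0.4),
                nu = NA_real_, resid_sd = stats::sd(diff(y)) / sqrt(2)))
  }
  l1 <- clip_to(-log(max(fit$ell1, 1e-6)) / dt, spec$lambda1$bounds)
  l2 <- clip_to(-log(max(fit$ell2, 1e-6)) / dt, spec$lambda2$bounds)
  amp <- max(fit$a1 + fit$a2, 1e-6)
  curve <- fit$a0 + fit$a1 * fit$ell1^i + fit$a2 * fit$ell2^i
  resid2 <- pmax((y - curve)^2, 1e-12)
  m_t <- curve - fit$a0          # bleachable signal above the offset
  xh <- pair_estimate(amp, m_t[-1], resid2[-1])
  xh <- xh[is.finite(xh) & xh > 0]
  nu_hat <- if (length(xh) >= 3) amp / stats::median(xh) else NA_real_
  list(cell = c(lambda1 = l1, lambda2 = l2,
                f = clip_to(fit$a0, spec$f$bounds),
                y0 = clip_to(amp, spec$y0$bounds),
                alpha = clip_to(fit$a2 / amp, c(0.01, 0.99))),
       nu = nu_hat,
       resid_sd = sqrt(mean(resid2)))
}

# Transformed (log / logit / identity) coordinates for optimization.
par_transform <- function(p, spec, names) {
  vapply(names, function(nm) {
    b <- spec[[nm]]$bounds
    v <- p[[nm]]
    if (nm == "alpha") stats::qlogis(clip_to(v, c(1e-6, 1 - 1e-6)))
    else if (b[1] > 0) log(clip_to(v, b))
    else clip_to(v, b)
  }, numeric(1))
}

par_untransform <- function(z, spec, names) {
  vapply(seq_along(names), function(i) {
    nm <- names[i]
    b <- spec[[nm]]$bounds
    if (nm == "alpha") stats::plogis(z[i])
    else if (b[1] > 0) clip_to(exp(z[i]), b)
    else clip_to(z[i], b)
  }, numeric(1)) -> v
  stats::setNames(v, names)
}

# Run BFGS (with a Nelder-Mead fallback) from each start; return the
# best parameter vector found, in transformed coordinates.
multistart_optim <- function(starts, obj, maxit) {
  best <- NULL
  for (z in starts) {
    cand <- tryCatch(
      stats::optim(z, obj, method = "BFGS",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(cand)) {
      cand <- tryCatch(
        stats::optim(z, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit)),
        error = function(e) list(par = z, value = obj(z)))
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  best
}

# Optimize one cell's block (optionally jointly with shared params)
# against its own likelihood. Starts from the incumbent, a structured
# alternative with no offset (f = 0, y0 = first frame, default rates),
# and random jitters; the structured start guards against bi-exponential
# fits that push the offset far from zero.
optimize_cell <- function(theta, j, data, spec, joint = FALSE,
                          budget = 400) {
  names_c <- cell_par_names
  obj_names <- if (joint) c(names_c, shared_par_names) else names_c
  obj <- function(z) {
    th <- theta
    v <- par_untransform(z, spec, obj_names)
    th$cells[j, ] <- v[names_c]
    if (joint) th$shared[shared_par_names] <- v[shared_par_names]
    ll <- cell_loglik(th, j, data)
    if (!is.finite(ll)) 1e12 else -ll
  }
  z_shared <- if (joint) par_transform(as.list(theta$shared), spec,
                                       shared_par_names) else NULL
  z0 <- c(par_transform(as.list(theta$cells[j, ]), spec, names_c),
          z_shared)
  y1 <- data$values[[j]][1]
  alt <- c(lambda1 = 0.003, lambda2 = 0.02, f = 0,
           y0 = clip_to(max(y1, 1), spec$y0$bounds), alpha = 0.4)
  z_alt <- c(par_transform(as.list(alt), spec, names_c), z_shared)
  starts <- list(z0, z_alt)
  n_extra <- max(0, floor(budget / 150) - 2)
  for (r in seq_len(n_extra)) {
    starts <- c(starts, list(z0 + stats::rnorm(length(z0), 0, 0.5)))
  }
  best <- multistart_optim(starts, obj, maxit = 200)
  par_untransform(best$par, spec, obj_names)
}

# Optimize the shared block against the full-data likelihood.
optimize_shared <- function(theta, data, spec, maxit = 200) {
  z0 <- par_transform(as.list(theta$shared), spec, shared_par_names)
  obj <- function(z) {
    th <- theta
    th$shared[shared_par_names] <-
      par_untransform(z, spec, shared_par_names)
    ll <- sum(all_cell_logliks(th, data))
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- list(z0, z0 + stats::rnorm(length(z0), 0, 0.3))
  best <- multistart_optim(starts, obj, maxit = maxit)
  par_untransform(best$par, spec, shared_par_names)
}

#' Nested-optimization initialization for the sampler
#'
#' Builds likelihood-informed chain starts in five steps: (1) per-cell
#' bi-exponential fits give heterogeneous starting values; (2) each cell's
#' full per-cell likelihood is optimized independently (bounded multistart
#' local search under a fixed evaluation budget); (3) shared parameters are
#' set to the medians of the per-cell fits; (4) block-coordinate ascent
#' alternates shared and per-cell optimization until the joint likelihood
#' stops improving; (5) half the chains start at that optimum, the rest at
#' optima of ascent runs started from random draws within the priors.
#'
#' @param traces Long-format traces.
#' @param spec A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#'
#' @return A list: `theta_hat` (the step-4 optimum), `starts` (list of
#'   `n_chains` parameter vectors), `ascent_loglik` (objective after each
#'   ascent sweep, non-decreasing), `data` (internal per-cell form).
#' @export
initialize_inference <- function(traces, spec = prior_spec(),
                                 config = mcmc_config(), seed = 1) {
  set.seed(as.integer(seed))
  data <- traces_to_data(traces, drop_first = config$drop_first)
  dt <- stats::median(diff(data$times))
  n_r <- data$n_cells

  # Step 1: bi-exponential starting values plus quick nu estimates
  step1 <- lapply(seq_len(n_r), function(j)
    init_cell_from_biexp(data$values[[j]], dt, spec))
  cells0 <- t(vapply(step1, function(s) s$cell, numeric(5)))
  colnames(cells0) <- cell_par_names

  # Shared start: brightness from the fluctuation estimates, constant
  # noise from the fit residuals, small linear/quadratic scales.
  nu_hats <- vapply(step1, function(s) s$nu, numeric(1))
  nu0 <- stats::median(nu_hats[is.finite(nu_hats)])
  if (!is.finite(nu0)) nu0 <- 1
  resid_sd <- stats::median(vapply(step1, function(s) s$resid_sd,
                                   numeric(1)))
  shared0 <- c(nu = clip_to(nu0, spec$nu$bounds),
               sigma_e0 = clip_to(resid_sd / 2, spec$sigma_e0$bounds),
               sigma_e1 = clip_to(0.01, spec$sigma_e1$bounds),
               sigma_e2 = clip_to(1e-5, spec$sigma_e2$bounds))
  theta <- make_theta(cells0, shared0)

  # Step 2: per-cell joint optimization
  per_cell_shared <- matrix(NA_real_, n_r, 4,
                            dimnames = list(NULL, shared_par_names))
  for (j in seq_len(n_r)) {
    v <- optimize_cell(theta, j, data, spec, joint = TRUE,
                       budget = config$init_budget)
    theta$cells[j, ] <- v[cell_par_names]
    per_cell_shared[j, ] <- v[shared_par_names]
  }

  # Step 3: medians of the homogeneous parameters, ignoring per-cell
  # fits that ran into a prior bound (a sign that cell's fit diverged)
  at_bound <- vapply(seq_len(n_r), function(j) {
    any(vapply(shared_par_names, function(nm) {
      b <- spec[[nm]]$bounds
      v <- per_cell_shared[j, nm]
      v <= b[1] * (1 + 1e-6) || v >= b[2] * (1 - 1e-6)
    }, logical(1)))
  }, logical(1))
  ok <- if (all(at_bound)) rep(TRUE, n_r) else !at_bound
  theta$shared[shared_par_names] <-
    apply(per_cell_shared[ok, , drop = FALSE], 2, stats::median)

  # Step 4: block-coordinate ascent
  ascent <- run_coordinate_ascent(theta, data, spec, config)
  theta_hat <- ascent$theta

  # Step 5: diverse chain starts
  n_chains <- config$n_chains
  starts <- vector("list", n_chains)
  n_opt <- ceiling(n_chains / 2)
  for (c_ in seq_len(n_chains)) {
    if (c_ <= n_opt) {
      starts[[c_]] <- theta_hat
    } else {
      th_r <- random_theta(n_r, spec)
      # seed random starts at the optimum's scale for y0/f so the
      # filter is not hopeless, then one cheap ascent sweep
      th_r$cells[, "y0"] <- theta_hat$cells[, "y0"] *
        exp(stats::rnorm(n_r, 0, 0.5))
      th_r$cells[, "f"] <- theta_hat$cells[, "f"]
      asc <- run_coordinate_ascent(th_r, data, spec,
                                   utils::modifyList(config,
                                                     list(max_sweeps = 1)))
      starts[[c_]] <- asc$theta
    }
  }
  list(theta_hat = theta_hat, starts = starts,
       ascent_loglik = ascent$history, data = data)
}

random_theta <- function(n_r, spec) {
  draw1 <- function(spec1) {
    b <- spec1$bounds
    if (spec1$kind == "scale_free" || b[1] > 0) {
      exp(stats::runif(1, log(b[1]), log(b[2])))
    } else {
      stats::runif(1, b[1], b[2])
    }
  }
  cells <- t(vapply(seq_len(n_r), function(j)
    vapply(cell_par_names, function(nm) draw1(spec[[nm]]), numeric(1)),
    numeric(5)))
  colnames(cells) <- cell_par_names
  shared <- vapply(shared_par_names, function(nm) draw1(spec[[nm]]),
                   numeric(1))
  make_theta(cells, shared)
}

run_coordinate_ascent <- function(theta, data, spec, config) {
  ll_cur <- sum(all_cell_logliks(theta, data))
  history <- ll_cur
  for (sweep in seq_len(config$max_sweeps)) {
    # per-cell blocks first: they must re-equilibrate to the current
    # shared parameters before the shared block is re-optimized
    for (j in seq_len(data$n_cells)) {
      v <- optimize_cell(theta, j, data, spec, joint = FALSE,
                         budget = 200)
      cand <- theta
      cand$cells[j, ] <- v[cell_par_names]
      d <- cell_loglik(cand, j, data) - cell_loglik(theta, j, data)
      if (is.finite(d) && d > 0) {
        theta <- cand
        ll_cur <- ll_cur + d
      }
    }
    cand <- theta
    cand$shared[shared_par_names] <- optimize_shared(theta, data, spec)
    ll_cand <- sum(all_cell_logliks(cand, data))
    if (is.finite(ll_cand) && ll_cand > ll_cur) {
      theta <- cand
      ll_cur <- ll_cand
    }
    history <- c(history, ll_cur)
    if (ll_cur - history[length(history) - 1] < 1e-3) break
  }
  list(theta = theta, history = history)
}

# Sampling ------------------------------------------------------------------

# One Metropolis-within-Gibbs sweep of a single chain at inverse
# temperature beta. Heterogeneous blocks are updated cell by cell (only
# that cell's likelihood is recomputed); the shared block is updated
# against the full-data likelihood. lambda1, lambda2, f, alpha move by
# normal proposals; y0, nu and the sigmas by log-normal proposals (with
# the Hastings asymmetry correction).
gibbs_sweep <- function(state, data, spec, beta, scales) {
  theta <- state$theta
  lls <- state$cell_lls
  acc_cell <- 0
  for (j in seq_len(data$n_cells)) {
    p <- theta$cells[j, ]
    prop <- p
    sc <- scales$cell[j]
    prop[["lambda1"]] <- p[["lambda1"]] +
      stats::rnorm(1, 0, sc * scales$lambda_unit)
    prop[["lambda2"]] <- p[["lambda2"]] +
      stats::rnorm(1, 0, sc * scales$lambda_unit)
    prop[["f"]] <- p[["f"]] + stats::rnorm(1, 0, sc * scales$f_unit)
    prop[["alpha"]] <- p[["alpha"]] + stats::rnorm(1, 0, sc * 0.1)
    prop[["y0"]] <- p[["y0"]] * exp(stats::rnorm(1, 0, sc))
    hastings <- log(prop[["y0"]]) - log(p[["y0"]])

    cand <- theta
    cand$cells[j, ] <- prop
    lp_new <- sum(vapply(cell_par_names, function(nm)
      log_prior_one(prop[[nm]], spec[[nm]]), numeric(1)))
    if (is.finite(lp_new)) {
      lp_old <- sum(vapply(cell_par_names, function(nm)
        log_prior_one(p[[nm]], spec[[nm]]), numeric(1)))
      ll_new <- if (beta > 0) cell_loglik(cand, j, data) else lls[j]
      log_a <- beta * (ll_new - lls[j]) + lp_new - lp_old + hastings
      if (beta == 0) log_a <- lp_new - lp_old + hastings
      if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
        theta <- cand
        lls[j] <- ll_new
        acc_cell <- acc_cell + 1
      }
    }
  }

  # shared block
  s <- theta$shared
  sc <- scales$shared
  prop <- s * exp(stats::rnorm(4, 0, sc))
  hastings <- sum(log(prop)) - sum(log(s))
  lp_new <- sum(vapply(shared_par_names, function(nm)
    log_prior_one(prop[[nm]], spec[[nm]]), numeric(1)))
  acc_shared <- 0
  if (is.finite(lp_new)) {
    lp_old <- sum(vapply(shared_par_names, function(nm)
      log_prior_one(s[[nm]], spec[[nm]]), numeric(1)))
    cand <- theta
    cand$shared[shared_par_names] <- prop
    lls_new <- if (beta > 0) all_cell_logliks(cand, data) else lls
    log_a <- beta * (sum(lls_new) - sum(lls)) + lp_new - lp_old + hastings
    if (beta == 0) log_a <- lp_new - lp_old + hastings
    if (all(is.finite(lls_new)) && is.finite(log_a) &&
        log(stats::runif(1)) < log_a) {
      theta <- cand
      lls <- lls_new
      acc_shared <- 1
    }
  }
  list(theta = theta, cell_lls = lls,
       acc_cell = acc_cell / data$n_cells, acc_shared = acc_shared)
}

# Adjacent-pair swap proposals with the standard tempered acceptance
# ratio; only likelihoods enter because all chains share the same prior.
swap_step <- function(chains, betas) {
  n <- length(chains)
  acc <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    L_k <- sum(chains[[k]]$cell_lls)
    L_k1 <- sum(chains[[k + 1]]$cell_lls)
    log_a <- (betas[k] - betas[k + 1]) * (L_k1 - L_k)
    if (is.finite(log_a) && log(stats::runif(1)) < log_a) {
      tmp <- chains[[k]]
      chains[[k]] <- chains[[k + 1]]
      chains[[k + 1]] <- tmp
      acc[k] <- 1
    }
  }
  list(chains = chains, acc = acc)
}

#' Sample the posterior over bleaching and noise parameters
#'
#' Runs the full inference: nested-optimization initialization, then
#' Metropolis-within-Gibbs sweeps on a ladder of tempered chains with
#' adjacent-pair swaps. Proposal scales follow a Robbins-Monro rule toward
#' the target acceptance rate, and the temperature ladder adapts its log
#' spacings toward the target swap rate; both adaptations stop at the end
#' of burn-in. Only the unit-temperature chain contributes samples.
#'
#' @param traces Long-format traces (already corrected).
#' @param spec A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#' @param likelihood Set `"off"` to sample the prior only (sampler
#'   diagnostics); default `"on"`.
#'
#' @return A list of class `posterior_samples`: `samples` (data.frame, one
#'   row per retained draw: shared parameters, per-cell parameters with
#'   `.cellN` suffixes, and `loglik`), `diagnostics` (acceptance and swap
#'   rates, final ladder and scales), `data_ids`.
#' @export
run_inference <- function(traces, spec = prior_spec(),
                          config = mcmc_config(), seed = 1,
                          likelihood = c("on", "off")) {
  likelihood <- match.arg(likelihood)
  seed <- as.integer(seed)
  init <- initialize_inference(traces, spec, config, seed = seed)
  set.seed(seed + 1L)
  data <- init$data
  n_chains <- config$n_chains
  n_iter <- config$iterations
  burn <- floor(config$burn_frac * n_iter)

  if (likelihood == "off") {
    ll_fun <- function(theta) rep(0, data$n_cells)
  } else {
    ll_fun <- function(theta) all_cell_logliks(theta, data)
  }

  # geometric initial ladder; beta_1 = 1
  betas <- 0.5^(seq_len(n_chains) - 1)
  log_gap <- diff(log(betas))  # negative log spacings
  chains <- lapply(seq_len(n_chains), function(c_) {
    th <- init$starts[[c_]]
    list(theta = th, cell_lls = ll_fun(th))
  })
  f_unit <- stats::median(vapply(data$values, function(y)
    stats::sd(y), numeric(1)))
  lambda_unit <- max(stats::median(init$theta_hat$cells[, c("lambda1",
                                                            "lambda2")]),
                     1e-4)
  scales <- lapply(seq_len(n_chains), function(c_)
    list(cell = rep(0.1, data$n_cells), shared = 0.05,
         f_unit = max(f_unit, 1), lambda_unit = lambda_unit))

  keep_iters <- seq(burn + 1, n_iter, by = config$thin)
  samples <- vector("list", length(keep_iters))
  k_out <- 0
  acc_cell_sum <- acc_shared_sum <- 0
  swap_sum <- numeric(max(n_chains - 1, 1))
  n_swaps <- 0

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn
    gamma <- 1 / max(it, 10)^0.6
    for (c_ in seq_len(n_chains)) {
      if (likelihood == "off") {
        res <- gibbs_sweep_prior_only(chains[[c_]], data, spec,
                                      scales[[c_]])
      } else {
        res <- gibbs_sweep(chains[[c_]], data, spec, betas[c_],
                           scales[[c_]])
      }
      chains[[c_]]$theta <- res$theta
      chains[[c_]]$cell_lls <- res$cell_lls
      if (adapting) {
        scales[[c_]]$cell <- pmin(pmax(
          scales[[c_]]$cell *
            exp(gamma * (res$acc_cell - config$target_accept)),
          1e-4), 10)
        scales[[c_]]$shared <- min(max(
          scales[[c_]]$shared *
            exp(gamma * (res$acc_shared - config$target_accept)),
          1e-4), 10)
      }
      if (c_ == 1) {
        acc_cell_sum <- acc_cell_sum + res$acc_cell
        acc_shared_sum <- acc_shared_sum + res$acc_shared
      }
    }
    if (n_chains > 1 && likelihood == "on") {
      sw <- swap_step(chains, betas)
      chains <- sw$chains
      swap_sum <- swap_sum + sw$acc
      n_swaps <- n_swaps + 1
      if (adapting) {
        # widen/narrow log spacings toward the target swap rate
        log_gap <- log_gap - gamma * (sw$acc - config$target_swap)
        log_gap <- pmin(pmax(log_gap, -5), -0.01)
        betas <- exp(cumsum(c(0, log_gap)))
      }
    }
    if (it > burn && (it - burn - 1) %% config$thin == 0) {
      k_out <- k_out + 1
      th <- chains[[1]]$theta
      row <- c(th$shared,
               stats::setNames(as.numeric(t(th$cells)),
                               paste0(rep(cell_par_names, data$n_cells),
                                      ".cell",
                                      rep(seq_len(data$n_cells),
                                          each = 5))),
               loglik = sum(chains[[1]]$cell_lls))
      samples[[k_out]] <- row
    }
  }
  samples <- as.data.frame(do.call(rbind, samples[seq_len(k_out)]))
  structure(
    list(samples = samples,
         diagnostics = list(
           acc_cell = acc_cell_sum / n_iter,
           acc_shared = acc_shared_sum / n_iter,
           swap_rates = if (n_swaps > 0) swap_sum / n_swaps else NULL,
           betas = betas,
           scales_cold = scales[[1]],
           ascent_loglik = init$ascent_loglik),
         data_ids = data$ids),
    class = "posterior_samples"
  )
}

# Prior-only sweep (likelihood switched off): same proposal machinery so
# the sampler itself can be validated against the analytic priors.
gibbs_sweep_prior_only <- function(state, data, spec, scales) {
  res <- gibbs_sweep(state, data, spec, beta = 0, scales = scales)
  res$cell_lls <- rep(0, data$n_cells)
  res
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples: %d draws, %d cells\n  acceptance: cells %.2f, shared %.2f\n",
    nrow(x$samples), length(x$data_ids),
    x$diagnostics$acc_cell, x$diagnostics$acc_shared))
  invisible(x)
}
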