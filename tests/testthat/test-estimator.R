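test_that("pairwise estimator arithmetic and algebraic identity", {
  expect_equal(pair_estimate(100, 50, 25), 100)
  expect_equal(pair_estimate(100, 100, 25), 0)  # no bleaching yet
  expect_true(is.na(pair_estimate(100, 50, 0)))
  # with exact moments the estimator returns x0 for every survival
  # fraction and brightness
  for (x0 in c(1e2, 1e6)) {
    for (nu in c(0.1, 1, 100)) {
      l <- seq(0.01, 0.99, by = 0.01)
      mean_t <- nu * x0 * l
      var_t <- nu^2 * x0 * l * (1 - l)
      xhat <- pair_estimate(nu * x0, mean_t, var_t)
      expect_equal(xhat, rep(x0, length(l)), tolerance = 1e-12)
    }
  }
})

test_that("estimate_cell produces one pair per positive time point", {
  sm2 <- structure(list(times = c(0, 10), mean = c(100, 50),
                        var = c(0, 25), fit = NULL),
                   class = "smoothed_trace")
  est <- estimate_cell(c(100, 55), sm2, "c1")
  expect_equal(nrow(est), 1)
  expect_equal(est$xhat0, 100)
  # 45-point trace gives 44 estimates
  times <- default_times()
  mean45 <- 1000 * exp(-0.004 * times)
  sm45 <- structure(list(times = times, mean = mean45,
                         var = rep(10, 45), fit = NULL),
                    class = "smoothed_trace")
  est45 <- estimate_cell(rnorm(45, mean45, 1), sm45, "c2")
  expect_equal(nrow(est45), 44)
  # with exact homogeneous moments every estimate equals x0
  x0 <- 400
  l <- exp(-0.004 * times)
  smx <- structure(list(times = times, mean = x0 * l,
                        var = x0 * l * (1 - l), fit = NULL),
                   class = "smoothed_trace")
  estx <- estimate_cell(x0 * l, smx, "c3")
  expect_equal(estx$xhat0, rep(x0, 44), tolerance = 1e-12)
  # dropping leading frames shortens the pair list
  est_drop <- estimate_cell(rnorm(45, mean45, 1), sm45, "c4",
                            drop_first = 5)
  expect_equal(nrow(est_drop), 40)
})

test_that("pooling takes the mode of the log10 KDE", {
  expect_equal(pool_and_mode(rep(250, 50))$mode, 250)
  set.seed(51)
  draws <- 10^rnorm(1e5, 4, 0.3)
  p <- pool_and_mode(draws)
  expect_lt(abs(p$mode - 1e4) / 1e4, 0.05)
  expect_equal(p$n_positive + p$n_negative, p$n_total)
  expect_error(pool_and_mode(rep(10, 5)), "too few")
  # negative estimates excluded but counted
  p2 <- pool_and_mode(c(draws[1:100], -5, -10))
  expect_equal(p2$n_negative, 2)
})

test_that("full synthetic cohort recovers the order of magnitude", {
  x0 <- 1e4
  sim <- simulate_cohort(60, seed = 52)
  res <- estimate_numbers(sim$traces, seed = 52)
  expect_lt(abs(log10(res$pooled$mode) - log10(x0)), 1)
  expect_gt(res$pooled$n_positive, 30)
})

test_that("predicted bias vanishes for homogeneous noise-free molecules
           and obeys the sign rule", {
  b0 <- bias_inputs(E_nu = 2, Var_nu = 0, E_ell = 0.5, Var_ell = 0,
                    E_nul = 1, Var_nul = 0, Cov_nu_nul = 0,
                    sigma_e2 = 0, x0 = 1e4)
  expect_equal(predicted_bias(b0)$epsilon, 0)
  expect_equal(predicted_bias(b0)$expected_xhat0, 1e4)
  # noise large enough makes epsilon positive: underestimation
  b1 <- bias_inputs(E_nu = 2, Var_nu = 0, E_ell = 0.5, Var_ell = 0,
                    E_nul = 1, Var_nul = 0.2, Cov_nu_nul = 0.1,
                    sigma_e2 = 5e4, x0 = 1e4)
  expect_gt(predicted_bias(b1)$epsilon, 0)
  expect_lt(predicted_bias(b1)$expected_xhat0, 1e4)
  # no noise with excess product variance: overestimation
  b2 <- bias_inputs(E_nu = 2, Var_nu = 0, E_ell = 0.5, Var_ell = 0,
                    E_nul = 1, Var_nul = 0.2, Cov_nu_nul = 0.1,
                    sigma_e2 = 0, x0 = 1e4)
  expect_lt(predicted_bias(b2)$epsilon, 0)
  # undefined when nothing bleaches
  b3 <- bias_inputs(E_nu = 2, Var_nu = 0, E_ell = 0.5, Var_ell = 0,
                    E_nul = 2, Var_nul = 0, Cov_nu_nul = 0,
                    sigma_e2 = 0, x0 = 10)
  expect_error(predicted_bias(b3), "no bleaching")
})

test_that("accuracy margins reproduce the three analytic conditions", {
  b <- bias_inputs(E_nu = 1, Var_nu = 0, E_ell = 0.5, Var_ell = 0,
                   E_nul = 0.5, Var_nul = 0, Cov_nu_nul = 0,
                   sigma_e2 = 0, x0 = 100)
  m <- accuracy_margins(b)
  expect_equal(m$homogeneous_nu$lhs, 0)
  expect_equal(m$homogeneous_nu$rhs, 0.25)
  # the homogeneous-brightness bound is loosest at mid-bleach
  rhs <- vapply(seq(0.05, 0.95, by = 0.05), function(el) {
    bb <- bias_inputs(E_nu = 1, Var_nu = 0, E_ell = el, Var_ell = 0,
                      E_nul = el, Var_nul = 0, Cov_nu_nul = 0,
                      sigma_e2 = 0, x0 = 100)
    accuracy_margins(bb)$homogeneous_nu$rhs
  }, numeric(1))
  expect_equal(which.max(rhs), 10)  # E[l] = 0.5
  # extreme brightness variation flips the last condition's sign
  b_bad <- bias_inputs(E_nu = 1, Var_nu = 2, E_ell = 0.5, Var_ell = 0,
                       E_nul = 0.5, Var_nul = 0.5, Cov_nu_nul = 0.5,
                       sigma_e2 = 0, x0 = 100)
  expect_lt(accuracy_margins(b_bad)$homogeneous_ell$rhs, 0)
})

test_that("Monte-Carlo bias of the estimator matches the analytic law", {
  # gamma brightness, beta survival, independent; 1000 replicate
  # ensembles of x0 molecules each
  set.seed(53)
  x0 <- 1e4
  shape <- 4
  nu_mean <- 2
  l_a <- 10
  l_b <- 10   # survival centered at 1/2
  sigma_e <- 100
  reps <- 1000
  xhat <- numeric(reps)
  for (k in seq_len(reps)) {
    nu <- rgamma(x0, shape, rate = shape / nu_mean)
    l <- rbeta(x0, l_a, l_b)
    num <- sum(nu * l) * sum(nu - nu * l)
    den <- sigma_e^2 + sum(nu^2 * l * (1 - l))
    xhat[k] <- num / den
  }
  E_nu <- nu_mean
  Var_nu <- nu_mean^2 / shape
  E_l <- l_a / (l_a + l_b)
  Var_l <- l_a * l_b / ((l_a + l_b)^2 * (l_a + l_b + 1))
  E_nul <- E_nu * E_l
  E_nu2 <- Var_nu + E_nu^2
  E_l2 <- Var_l + E_l^2
  Var_nul <- E_nu2 * E_l2 - E_nul^2
  Cov <- E_nu2 * E_l - E_nu * E_nul
  b <- bias_inputs(E_nu, Var_nu, E_l, Var_l, E_nul, Var_nul, Cov,
                   sigma_e^2, x0)
  pred <- predicted_bias(b)$expected_xhat0
  se <- sd(xhat) / sqrt(reps)
  expect_lt(abs(mean(xhat) - pred), 3 * se + 0.002 * pred)
})

test_that("reference count and maturation fraction calculations", {
  expect_equal(molecules_from_concentration(0, 5), 0)
  # 1 nM in 1/(N_A * 1e-24) fl is one molecule
  one <- molecules_from_concentration(1, 1 / (6.02214076e23 * 1e-24))
  expect_equal(one, 1, tolerance = 1e-12)
  fus3 <- sum(molecules_from_concentration(c(180, 3 * 180), c(42 - 3, 3)))
  expect_equal(signif(fus3, 2), 5200)
  expect_equal(mature_fraction(45, 45), 0.5)
  expect_equal(round(mature_fraction(45, 100), 1), 0.7)
  expect_equal(mature_fraction(45, 1e12), 1, tolerance = 1e-10)
})

test_that("the pairwise estimator is the maximum-likelihood point", {
  # worked instance: the likelihood chain over the latent brightness and
  # survival peaks exactly at the closed-form estimate
  y0 <- 2000
  mu_y <- 800
  var_y <- 900
  expected <- mu_y * (y0 - mu_y) / var_y
  opt <- mle_x0(y0, mu_y, var_y)
  expect_lt(abs(opt - expected) / expected, 1e-6)
  # profile is unimodal around the peak
  grid <- expected * c(0.5, 0.9, 1, 1.1, 2)
  ll <- x0_loglik_profile(grid, y0, mu_y, var_y)
  expect_equal(which.max(ll), 3)
})
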