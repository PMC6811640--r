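test_that("fitted hyperparameters always respect the box bounds", {
  b <- gp_bounds()
  set.seed(31)
  for (k in 1:4) {
    times <- default_times(20)
    y <- 1e4 * exp(-0.005 * times) + rnorm(20, 0, 50 * k)
    fit <- fit_gp(times, y, seed = 100 + k)
    expect_true(fit$converged)
    expect_gte(fit$theta0, b$theta0[1])
    expect_lte(fit$theta0, b$theta0[2])
    expect_gte(fit$theta1, b$theta1[1])
    expect_lte(fit$theta1, b$theta1[2])
    expect_gte(fit$theta2, b$theta2[1])
    expect_lte(fit$theta2, b$theta2[2])
  }
})

test_that("GP mean is linear in the observations at fixed hyperparameters", {
  set.seed(32)
  times <- default_times(15)
  y <- 5000 * exp(-0.01 * times) + rnorm(15, 0, 100)
  fit <- fit_gp(times, y, seed = 1)
  fit$offset <- 0  # fix the prior mean so the map is strictly linear
  m1 <- predict_mean(times, y, fit)
  m2 <- predict_mean(times, 2 * y, fit)
  expect_equal(m2, 2 * m1, tolerance = 1e-10)
})

test_that("noise-dominated and interpolation limits behave as expected", {
  times <- default_times(12)
  set.seed(33)
  y <- rnorm(12, 0, 1)
  # huge forced noise, small signal variance: mean shrinks to the offset
  fit <- structure(list(theta0 = 1e3, theta1 = 1e-4, theta2 = 1e10,
                        offset = mean(y), converged = TRUE),
                   class = "gp_fit")
  m <- predict_mean(times, y, fit)
  expect_lt(max(abs(m - mean(y))), 1e-3)
  # tiny noise on smooth exactly-representable data: near interpolation
  y2 <- 1e4 * exp(-((times - 200) / 150)^2)
  fit2 <- structure(list(theta0 = 1e8, theta1 = 1e-4, theta2 = 10,
                         offset = mean(y2), converged = TRUE),
                    class = "gp_fit")
  m2 <- predict_mean(times, y2, fit2)
  expect_lt(max(abs(m2 - y2)) / max(y2), 1e-3)
})

test_that("smoothing white noise beats the raw data at recovering a
           constant", {
  set.seed(34)
  times <- default_times(40)
  truth <- 5e4
  y <- truth + rnorm(40, 0, 500)
  fit <- fit_gp(times, y, seed = 2)
  m <- predict_mean(times, y, fit)
  expect_lt(mean((m - truth)^2), mean((y - truth)^2))
})

test_that("GP smoothing of a bleaching trace beats the raw data", {
  np <- camera_noise()
  cell <- homog_cell(x0 = 1e5, lambda = 0.004)
  times <- default_times()
  lt <- simulate_pools(cell, times, seed = 35)
  y <- add_noise(lt$counts1 + lt$counts2, cell, np, seed = 36)
  truth_mean <- np$nu * theoretical_moments(1e5, 0.004, times)$mean
  sm <- smooth_trace(times, y, seed = 37)
  expect_lt(sqrt(mean((sm$mean - truth_mean)^2)),
            sqrt(mean((y - truth_mean)^2)))
})

test_that("residual variances are element-wise squared residuals", {
  m <- c(1, 2, 3)
  expect_equal(residual_variance(m, m), c(0, 0, 0))
  expect_equal(residual_variance(m + 2, m), c(4, 4, 4))
  # averaged over many cells, squared residuals approach the true
  # fluctuation-plus-noise variance
  np <- noise_params(10, sigma_e0 = 50)
  cell <- homog_cell(x0 = 5000, lambda = 0.005)
  times <- default_times(30)
  t_idx <- 15
  reps <- 300
  set.seed(38)
  rv <- numeric(reps)
  for (k in seq_len(reps)) {
    lt <- simulate_pools(cell, times, seed = 400 + k)
    y <- add_noise(lt$counts1 + lt$counts2, cell, np, seed = 900 + k)
    mu <- np$nu * theoretical_moments(5000, 0.005, times)$mean
    rv[k] <- residual_variance(y, mu)[t_idx]
  }
  th <- theoretical_moments(5000, 0.005, times[t_idx])
  v_true <- np$nu^2 * th$var + np$sigma_e0^2
  # squared residuals are chi-square scattered; the mean has sd ~ v*sqrt(2/n)
  expect_lt(abs(mean(rv) - v_true) / v_true, 4 * sqrt(2 / reps))
})

test_that("forcing theta2 low inflates the pooled estimate and forcing it
           high deflates it", {
  # the known bias direction of smoothing-based variance estimation
  set.seed(39)
  x0 <- 1e4
  sim <- simulate_cohort(15, hyper = point_hyper(x0 = x0), seed = 40)
  run_forced <- function(theta2) {
    ests <- c()
    for (id in unique(sim$traces$cell_id)) {
      tr <- sim$traces[sim$traces$cell_id == id, ]
      fit <- fit_gp(tr$time_s, tr$fluorescence, seed = 41)
      fit$theta2 <- theta2
      m <- predict_mean(tr$time_s, tr$fluorescence, fit)
      sm <- structure(list(times = tr$time_s, mean = m,
                           var = residual_variance(tr$fluorescence, m),
                           fit = fit), class = "smoothed_trace")
      ests <- rbind(ests, estimate_cell(tr$fluorescence, sm, id))
    }
    pool_and_mode(ests)$mode
  }
  lo <- run_forced(10)     # residuals vanish -> variance too small -> high
  hi <- run_forced(1e9)    # mean ignores data -> variance too big -> low
  expect_gt(lo, x0)
  expect_lt(hi, x0 * 0.9)
  expect_gt(lo, hi)
})
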