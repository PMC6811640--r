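# Shared fixtures built in code: small cohorts, noise settings, and a
# homogeneous single-pool cell used across tests.

camera_noise <- function() noise_params(20, 136.6, 1.31, 0.0027)

homog_cell <- function(x0 = 1e4, lambda = 0.003, f = 0) {
  cell_params(lambda1 = lambda, lambda2 = 0, x0 = x0, alpha = 0, f = f)
}

# Point-mass hyperparameters: every cell identical.
point_hyper <- function(lambda1 = 0.003, lambda2 = 0.0105, x0 = 1e4,
                        alpha = 0.4, f = 0) {
  list(
    lambda1 = function(n) rep(lambda1, n),
    lambda2 = function(n) rep(lambda2, n),
    x0      = function(n) rep(x0, n),
    alpha   = function(n) rep(alpha, n),
    f       = function(n) rep(f, n)
  )
}

default_times <- function(n = 45, dt = 10) seq(0, by = dt, length.out = n)

# Exact bi-exponential curve for fit-recovery tests.
biexp_curve <- function(n, a0, a1, a2, l1, l2) {
  i <- seq_len(n) - 1
  a0 + a1 * l1^i + a2 * l2^i
}
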