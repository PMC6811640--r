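# Independent oracles used by both the unit and acceptance suites.

# Joint Gaussian log density via Cholesky (no extra dependencies).
dmvnorm_log <- function(y, mu, S) {
  ch <- chol(S)
  z <- forwardsolve(t(ch), y - mu)
  -0.5 * (length(y) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Brute-force observation covariance for the two-pool model with constant
# measurement noise: Cov(x_s, x_t) = Var(x_min) * exp(-lambda (t - s)) per
# pool (linear first-order decay), pools independent from a delta start.
brute_force_loglik <- function(y, times, cell, noise) {
  nu <- noise$nu
  V <- noise$sigma_e0^2
  n <- length(times)
  pools <- list(
    list(x0 = cell$x0 * (1 - cell$alpha), lam = cell$lambda1),
    list(x0 = cell$x0 * cell$alpha, lam = cell$lambda2))
  mu <- numeric(n)
  S <- matrix(0, n, n)
  for (p in pools) {
    l_t <- exp(-p$lam * times)
    mu <- mu + nu * p$x0 * l_t
    v_t <- p$x0 * l_t * (1 - l_t)
    for (i in seq_len(n)) {
      for (j in i:n) {
        c_ij <- v_t[i] * exp(-p$lam * (times[j] - times[i]))
        S[i, j] <- S[i, j] + nu^2 * c_ij
        if (j > i) S[j, i] <- S[j, i] + nu^2 * c_ij
      }
    }
  }
  diag(S) <- diag(S) + V
  dmvnorm_log(y - cell$f, mu, S)
}
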