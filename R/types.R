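#' Per-cell bleaching parameters
#'
#' Bundles the heterogeneous parameters of the two-pool bleaching model for
#' one cell: two first-order bleach rates, the total initial molecule count,
#' the fraction of molecules in the second (typically faster) pool, and any
#' residual autofluorescence offset left after correction.
#'
#' @param lambda1,lambda2 Pool bleach rates (1/s), both `>= 0`.
#' @param x0 Total initial number of molecules, `>= 0`.
#' @param alpha Fraction of `x0` assigned to pool 2, in `[0, 1]`.
#' @param f Residual autofluorescence offset (camera units).
#'
#' @return An object of class `cell_params`.
#' @export
#' @examples
#' cell_params(lambda1 = 0.003, lambda2 = 0.02, x0 = 1e4, alpha = 0.4)
cell_params <- function(lambda1, lambda2, x0, alpha, f = 0) {
  stopifnot(
    is.numeric(lambda1), lambda1 >= 0,
    is.numeric(lambda2), lambda2 >= 0,
    is.numeric(x0), x0 >= 0,
    is.numeric(alpha), alpha >= 0, alpha <= 1,
    is.numeric(f), is.finite(f)
  )
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, x0 = x0,
         alpha = alpha, f = f),
    class = "cell_params"
  )
}

#' Homogeneous measurement model parameters
#'
#' The brightness per molecule and the three scales of the quadratic
#' measurement-noise model: observed fluorescence is normal with mean
#' `nu * x + f` and variance
#' `sigma_e0^2 + nu * x * sigma_e1^2 + (nu * x * sigma_e2)^2`
#' for total unbleached count `x`.
#'
#' @param nu Brightness per molecule (camera units / molecule), `> 0`.
#' @param sigma_e0 Constant noise scale (camera units), `>= 0`.
#' @param sigma_e1 Scale of the linear (shot-noise-like) variance term, `>= 0`.
#' @param sigma_e2 Scale of the quadratic variance term, `>= 0`.
#'
#' @return An object of class `noise_params`.
#' @export
#' @examples
#' noise_params(nu = 20, sigma_e0 = 136.6, sigma_e1 = 1.31, sigma_e2 = 0.0027)
noise_params <- function(nu, sigma_e0 = 0, sigma_e1 = 0, sigma_e2 = 0) {
  stopifnot(
    is.numeric(nu), nu > 0,
    sigma_e0 >= 0, sigma_e1 >= 0, sigma_e2 >= 0
  )
  structure(
    list(nu = nu, sigma_e0 = sigma_e0, sigma_e1 = sigma_e1,
         sigma_e2 = sigma_e2),
    class = "noise_params"
  )
}

#' Fully heterogeneous molecule ensemble
#'
#' Describes a population of `x0` molecules in one cell where every molecule
#' carries its own brightness `nu_i` and its own bleach rate `lambda_i`,
#' drawn from marginal distributions given as quantile functions and coupled
#' (optionally) through a Gaussian copula with the stated rank correlation.
#'
#' @param x0 Number of molecules, `>= 1`.
#' @param brightness_q Quantile function for per-molecule brightness;
#'   must return strictly positive values.
#' @param rate_q Quantile function for per-molecule bleach rate;
#'   must return non-negative values.
#' @param rho Gaussian-copula correlation between brightness and rate,
#'   in `[-1, 1]`. Zero (default) means independent.
#'
#' @return An object of class `molecule_ensemble`.
#' @export
#' @examples
#' molecule_ensemble(1000,
#'   brightness_q = function(p) qgamma(p, shape = 4, rate = 0.2),
#'   rate_q = function(p) rep(0.01, length(p)))
molecule_ensemble <- function(x0, brightness_q, rate_q, rho = 0) {
  stopifnot(
    is.numeric(x0), x0 >= 1,
    is.function(brightness_q), is.function(rate_q),
    is.numeric(rho), rho >= -1, rho <= 1
  )
  structure(
    list(x0 = as.integer(round(x0)), brightness_q = brightness_q,
         rate_q = rate_q, rho = rho),
    class = "molecule_ensemble"
  )
}

#' Gaussian latent state of the two bleaching pools
#'
#' Mean vector and covariance of the two unbleached pools under the linear
#' noise approximation.
#'
#' @param mu Length-2 mean vector (pool 1, pool 2).
#' @param Sigma 2x2 covariance matrix, symmetric positive semi-definite.
#'
#' @return An object of class `gaussian_state`.
#' @export
gaussian_state <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- matrix(as.numeric(Sigma), 2, 2)
  stopifnot(length(mu) == 2, all(is.finite(mu)), all(is.finite(Sigma)))
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(mu = mu, Sigma = Sigma), class = "gaussian_state")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "cell_params: lambda1=%.4g/s lambda2=%.4g/s x0=%.4g alpha=%.3f f=%.4g\n",
    x$lambda1, x$lambda2, x$x0, x$alpha, x$f))
  invisible(x)
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "noise_params: nu=%.4g sigma_e0=%.4g sigma_e1=%.4g sigma_e2=%.4g\n",
    x$nu, x$sigma_e0, x$sigma_e1, x$sigma_e2))
  invisible(x)
}
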