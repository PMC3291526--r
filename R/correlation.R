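#' Build a random input cross-correlation matrix
#'
#' Constructs a random symmetric positive semi-definite cross-correlation
#' matrix with unit diagonal, used to describe the second-order statistics of
#' the external stimulus ensemble. The matrix is formed as `A %*% t(A)` from a
#' standard-normal random matrix and rescaled to unit diagonal.
#'
#' The number of columns of the random factor (`dof`) controls conditioning:
#' with `dof = n` the product is a Wishart matrix that is nearly singular
#' with appreciable probability, which would violate the positive-definite
#' stimulus assumption underlying the fixed-point analysis of the linear
#' engine. The default `dof = 2 * n` keeps the smallest eigenvalue bounded
#' well away from zero while leaving substantial random correlation
#' structure between channels.
#'
#' @param n Number of input channels (lower-layer units).
#' @param dof Number of columns of the random factor `A`.
#' @return An `n` by `n` correlation matrix (symmetric, PSD, unit diagonal).
#' @examples
#' set.seed(1)
#' C <- build_input_correlation(10)
#' min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
#' @export
build_input_correlation <- function(n, dof = 2L * n) {
  stopifnot(n >= 1, dof >= 1)
  A <- matrix(rnorm(n * dof), n, dof)
  C <- A %*% t(A)
  d <- sqrt(diag(C))
  C <- C / outer(d, d)
  # enforce exact symmetry and unit diagonal against round-off
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Symmetric matrix square root
#'
#' Returns the symmetric positive semi-definite square root of a symmetric
#' PSD matrix via its eigendecomposition, with small negative eigenvalues
#' (round-off) clipped to zero.
#'
#' @param C A symmetric PSD matrix.
#' @param tol Tolerance for negative eigenvalues; values below `-tol * max`
#'   raise an error.
#' @return A matrix `S` with `S %*% S` equal to `C` up to round-off.
#' @export
sym_sqrt <- function(C, tol = 1e-8) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  mx <- max(abs(e$values), 1)
  if (min(e$values) < -tol * mx) {
    stop("sym_sqrt: matrix is not positive semi-definite")
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Sample zero-mean Gaussian vectors with a prescribed cross-correlation
#'
#' Colours independent standard normal draws with the symmetric square root
#' of `C` so that the population covariance of the returned vectors is `C`.
#'
#' @param C Cross-correlation (covariance) matrix.
#' @param n_draws Number of vectors to draw.
#' @return A matrix with `n_draws` columns, each one sample.
#' @export
sample_correlated_gaussian <- function(C, n_draws = 1L) {
  S <- sym_sqrt(C)
  Z <- matrix(rnorm(nrow(C) * n_draws), nrow(C), n_draws)
  S %*% Z
}

#' Sample per-presentation external input strengths
#'
#' Draws the vector of mean external input rates for the lower-layer units
#' used during one stimulus presentation: a correlated Gaussian vector
#' (coloured with the symmetric square root of `C_input`) centred at
#' `J_mean` spikes/s, rectified at zero so rates are non-negative. Across many
#' draws the empirical cross-correlation of the underlying (pre-rectification)
#' vectors equals `C_input`; rectification introduces a small bias that is
#' negligible at the default operating point, where `J_mean` is many standard
#' deviations above zero.
#'
#' @param C_input Input cross-correlation matrix (unit diagonal).
#' @param J_mean Mean input rate, spikes/s.
#' @param rate_sd Standard deviation of the per-unit rate around `J_mean`,
#'   spikes/s. The default scales with `J_mean` so stimuli differ appreciably
#'   across units and presentations.
#' @return A numeric vector of non-negative rates, one per lower-layer unit.
#' @export
sample_input_strengths <- function(C_input, J_mean = 20000, rate_sd = J_mean / 4) {
  x <- as.vector(sample_correlated_gaussian(C_input, 1L))
  pmax(J_mean + rate_sd * x, 0)
}
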