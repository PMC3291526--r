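#' Generate a well-conditioned random bottom-up weight matrix
#'
#' Builds the fixed feedforward (bottom-up) weight matrix `Q` connecting the
#' lower layer to the higher layer. Because the learned top-down weights are
#' expected to approach a scaled inverse of `Q`, the construction is designed
#' to produce a well-conditioned matrix: a uniform random matrix is (optionally)
#' smoothed with a circular Gaussian filter, its polar decomposition
#' `R = U P` is computed (`U` orthogonal, `P` symmetric positive
#' semi-definite), and the two factors are recombined as `U + epsilon * P`,
#' which is a small perturbation of an orthogonal matrix. The result is then
#' normalized by dividing each column by its mean, dividing the whole matrix
#' by its maximum entry, and multiplying by 5, so that the largest entry of
#' the returned matrix equals 5 exactly.
#'
#' Degenerate draws (rank-deficient random matrix, or a column whose mean is
#' numerically zero after recombination) are discarded and regenerated from
#' fresh draws; each retry is reported with a message.
#'
#' @param n_lower Number of lower-layer units (columns of `Q`).
#' @param n_higher Number of higher-layer units (rows of `Q`).
#' @param epsilon Weight of the positive semi-definite factor in the
#'   recombination `U + epsilon * P`. Must be positive.
#' @param smooth_width Standard deviation, in matrix pixels, of the circular
#'   Gaussian smoothing filter applied to the initial random draw, or `NULL`
#'   to skip smoothing.
#' @param max_retries Maximum number of fresh draws attempted when a draw is
#'   degenerate.
#' @return An `n_higher` by `n_lower` numeric matrix with maximum entry 5.
#' @examples
#' set.seed(1)
#' Q <- generate_bottom_up_matrix(20, 20, epsilon = 0.1)
#' max(Q)  # exactly 5
#' @export
generate_bottom_up_matrix <- function(n_lower, n_higher, epsilon = 0.1,
                                      smooth_width = NULL, max_retries = 20L) {
  stopifnot(n_lower >= 1, n_higher >= 1, epsilon > 0)
  for (attempt in seq_len(max_retries)) {
    R <- matrix(runif(n_higher * n_lower), n_higher, n_lower)
    if (!is.null(smooth_width)) {
      R <- smooth_circular_gaussian(R, smooth_width)
    }
    pd <- tryCatch(polar_decomposition(R), error = function(e) NULL)
    if (is.null(pd)) {
      message("generate_bottom_up_matrix: degenerate polar decomposition, retrying")
      next
    }
    # square case: orthogonal factor plus a small multiple of the positive
    # factor; rectangular case: the same perturbation composed through U so
    # the shapes conform
    Qt <- if (n_lower == n_higher) {
      pd$U + epsilon * pd$P
    } else {
      pd$U %*% (diag(n_lower) + epsilon * pd$P)
    }
    col_means <- colMeans(Qt)
    if (any(abs(col_means) < 1e-8)) {
      message("generate_bottom_up_matrix: near-zero column mean, retrying")
      next
    }
    Q <- sweep(Qt, 2, col_means, "/")
    mx <- max(Q)
    if (!is.finite(mx) || mx <= 0) {
      message("generate_bottom_up_matrix: non-positive maximum, retrying")
      next
    }
    Q <- Q / mx * 5
    return(Q)
  }
  stop("generate_bottom_up_matrix: failed to generate a non-degenerate matrix after ",
       max_retries, " attempts")
}

#' Polar decomposition of a real matrix
#'
#' Factors `R = U P` with `U` orthogonal (unitary) and `P` symmetric positive
#' semi-definite, computed from the singular value decomposition.
#'
#' @param R A real matrix.
#' @param tol Relative tolerance below which the smallest singular value is
#'   considered zero (rank-deficient input raises an error).
#' @return A list with components `U` and `P`.
#' @export
polar_decomposition <- function(R, tol = 1e-10) {
  sv <- svd(R)
  if (max(sv$d) == 0 || min(sv$d) < tol * max(sv$d)) {
    stop("polar_decomposition: matrix is numerically rank-deficient")
  }
  U <- sv$u %*% t(sv$v)
  P <- sv$v %*% (sv$d * t(sv$v))
  list(U = U, P = P)
}

#' Smooth a matrix with a circular (wrap-around) Gaussian filter
#'
#' Convolves the matrix with a two-dimensional Gaussian kernel on a torus,
#' i.e. with periodic boundary conditions in both dimensions, via FFT.
#'
#' @param A A numeric matrix.
#' @param width Standard deviation of the Gaussian kernel, in pixels.
#' @return A matrix of the same dimensions.
#' @export
smooth_circular_gaussian <- function(A, width) {
  stopifnot(is.matrix(A), width > 0)
  nr <- nrow(A); nc <- ncol(A)
  # circular distances from index 1 along each axis
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  K <- exp(-(outer(dr^2, dc^2, "+")) / (2 * width^2))
  K <- K / sum(K)
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  out
}
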