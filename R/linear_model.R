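#' Two-layer linear network
#'
#' Bundles the bottom-up weight matrix `Q` (`n_higher` x `n_lower`) and the
#' top-down weight matrix `W` (`n_lower` x `n_higher`) of the linear
#' firing-rate model. Activity propagates as `H = Q L` (up) and `L = W H`
#' (down) at alternating time-points.
#'
#' @param Q Bottom-up weight matrix, `n_higher` by `n_lower`.
#' @param W Top-down weight matrix, `n_lower` by `n_higher`.
#' @return An object of class `linear_network`.
#' @export
linear_network <- function(Q, W) {
  stopifnot(is.matrix(Q), is.matrix(W),
            nrow(Q) == ncol(W), ncol(Q) == nrow(W),
            all(is.finite(Q)), all(is.finite(W)))
  structure(list(Q = Q, W = W,
                 n_lower = ncol(Q), n_higher = nrow(Q)),
            class = "linear_network")
}

#' @export
print.linear_network <- function(x, ...) {
  cat("Two-layer linear network:", x$n_lower, "lower units,",
      x$n_higher, "higher units\n")
  cat("  max |eig(WQ)| =", format(max_loop_gain(x$Q, x$W), digits = 4), "\n")
  invisible(x)
}

#' Specification of a pairwise plasticity rule for the linear engine
#'
#' @param orientation `"classical"` (pre-before-post potentiates) or
#'   `"reverse"` (post-before-pre potentiates). The higher-layer unit is
#'   always pre-synaptic and the lower-layer unit post-synaptic at a
#'   top-down synapse.
#' @param alpha Depression/potentiation ratio; `alpha > 1` means depression
#'   dominates. The depressing sum is always the one multiplied by `alpha`.
#' @param mu Learning rate.
#' @param update_mode `"expected"` to iterate the deterministic expected
#'   update computed directly from the stimulus cross-correlation matrix, or
#'   `"per_stimulus"` to draw an input vector each presentation.
#' @param multiplicative If `TRUE`, use the soft-bound multiplicative rule:
#'   the potentiating accumulation is scaled entry-wise by `(W_max - w)`
#'   and the depressing one by `|w|`.
#' @param W_max Weight bound used by the multiplicative factors (the linear
#'   engine uses no hard clipping).
#' @return An object of class `linear_rule`.
#' @export
linear_rule <- function(orientation = c("reverse", "classical"),
                        alpha = 3, mu = 3e-4,
                        update_mode = c("expected", "per_stimulus"),
                        multiplicative = FALSE, W_max = 30) {
  orientation <- match.arg(orientation)
  update_mode <- match.arg(update_mode)
  stopifnot(alpha > 0, mu > 0, W_max > 0)
  structure(list(orientation = orientation, alpha = alpha, mu = mu,
                 update_mode = update_mode,
                 multiplicative = isTRUE(multiplicative), W_max = W_max),
            class = "linear_rule")
}

#' Simulate activity during one stimulus presentation (linear engine)
#'
#' The external input `x` sets the lower-layer activity at the first
#' time-point; activity then alternates between the layers,
#' `H(t+1) = Q L(t)` at odd `t` and `L(t+1) = W H(t)` at even `t`, with the
#' weights held constant within the presentation (plasticity is slow relative
#' to a presentation). Non-finite activity caused by a strong loop is flagged
#' rather than raised; callers classify such runs as extreme.
#'
#' @param net A [linear_network].
#' @param x External input vector, length `n_lower`.
#' @param T Number of time-points (odd values give equal numbers of
#'   upward and downward transitions).
#' @return A list of class `activity_trajectory` with `L` (lower activity,
#'   one column per odd time-point), `H` (higher activity, one column per
#'   even time-point), `T`, and `finite` (FALSE if activity overflowed).
#' @export
simulate_presentation_linear <- function(net, x, T = 9L) {
  stopifnot(inherits(net, "linear_network"), length(x) == net$n_lower, T >= 3)
  n_L_steps <- (T + 1L) %/% 2L   # time-points 1, 3, 5, ...
  n_H_steps <- T %/% 2L          # time-points 2, 4, ...
  L <- matrix(0, net$n_lower, n_L_steps)
  H <- matrix(0, net$n_higher, n_H_steps)
  L[, 1] <- x
  for (k in seq_len(n_H_steps)) {
    H[, k] <- net$Q %*% L[, k]
    if (k + 1L <= n_L_steps) L[, k + 1L] <- net$W %*% H[, k]
  }
  structure(list(L = L, H = H, T = as.integer(T),
                 finite = all(is.finite(L)) && all(is.finite(H))),
            class = "activity_trajectory")
}

#' Plasticity update from one trajectory (linear engine)
#'
#' Accumulates, over every pair of adjacent time-points, the joint activity
#' of the pre-synaptic higher-layer unit and the post-synaptic lower-layer
#' unit. Pairs where the higher unit is active one step before the lower unit
#' ("pre-before-post") and pairs where the lower unit is active one step
#' before the higher unit ("post-before-pre") enter with opposite signs: for
#' the classical orientation pre-before-post potentiates and post-before-pre
#' depresses with weight `alpha`; for the reverse orientation the roles are
#' swapped. The result is scaled by the learning rate `mu`.
#'
#' @param rule A [linear_rule].
#' @param trajectory An `activity_trajectory` from
#'   [simulate_presentation_linear].
#' @return The weight change `Delta W`, an `n_lower` by `n_higher` matrix.
#' @export
stdp_delta_linear <- function(rule, trajectory) {
  stopifnot(inherits(rule, "linear_rule"),
            inherits(trajectory, "activity_trajectory"))
  sums <- linear_pair_sums(trajectory)
  compose_linear_delta(rule, sums$pre_post, sums$post_pre, NULL)
}

# Adjacent-time-point joint-activity sums of one trajectory, from the
# top-down synapse's viewpoint (higher = pre, lower = post).
linear_pair_sums <- function(trajectory) {
  L <- trajectory$L; H <- trajectory$H
  m <- ncol(H)
  pre_post <- matrix(0, nrow(L), nrow(H))  # H(t) then L(t+1)
  post_pre <- matrix(0, nrow(L), nrow(H))  # L(t) then H(t+1)
  for (k in seq_len(m)) {
    post_pre <- post_pre + L[, k] %*% t(H[, k])
    if (k + 1L <= ncol(L)) pre_post <- pre_post + L[, k + 1L] %*% t(H[, k])
  }
  list(pre_post = pre_post, post_pre = post_pre)
}

# Orientation, bias and the optional multiplicative soft bound applied to a
# pair of accumulation matrices.  `W` is only needed for the multiplicative
# factors; rate defaults to the rule's mu.
compose_linear_delta <- function(rule, pre_post, post_pre, W, rate = rule$mu) {
  if (rule$orientation == "classical") {
    pot <- pre_post; dep <- post_pre
  } else {
    pot <- post_pre; dep <- pre_post
  }
  if (isTRUE(rule$multiplicative)) {
    f <- multiplicative_stdp_factors(W, rule$W_max)
    rate * (pot * f$pot_factor - rule$alpha * dep * f$dep_factor)
  } else {
    rate * (pot - rule$alpha * dep)
  }
}

#' Expected plasticity update computed from the stimulus correlation
#'
#' Computes the presentation-averaged weight change of the linear engine in
#' closed form: with `M = W Q` and `C` the stimulus cross-correlation matrix,
#' the accumulated post-before-pre joint activity averages to
#' `S %*% t(Q)` with `S = sum_k M^k C t(M)^k` (k = 0 .. (T-3)/2), and the
#' pre-before-post side averages to `M %*% S %*% t(Q)`. The expected update
#' is therefore `mu * (I - alpha M) S t(Q)` for the reverse orientation and
#' `mu * (M - alpha I) S t(Q)` for the classical one, which vanishes exactly
#' when `M = I/alpha` (reverse) or `M = alpha I` (classical).
#'
#' @param net A [linear_network].
#' @param C Stimulus cross-correlation matrix, `n_lower` square.
#' @param rule A [linear_rule].
#' @param T Presentation length in time-points; must be odd so upward and
#'   downward transitions are paired.
#' @return The expected `Delta W` matrix.
#' @export
expected_stdp_delta <- function(net, C, rule, T = 9L) {
  sums <- expected_pair_sums(net, C, T)
  compose_linear_delta(rule, sums$pre_post, sums$post_pre, net$W)
}

# Presentation-averaged pair sums.  With M = W Q and
# S = sum_{k=0}^{m-1} M^k C t(M)^k (m = (T-1)/2 full round trips):
# post-before-pre averages to S t(Q), pre-before-post to M S t(Q).
# From the bottom-up synapse's viewpoint the same adjacent pairs give
# pre-before-post = Q S and post-before-pre = Q S t(M).
expected_pair_sums <- function(net, C, T) {
  stopifnot(inherits(net, "linear_network"), T >= 3, T %% 2 == 1,
            nrow(C) == net$n_lower, ncol(C) == net$n_lower)
  M <- net$W %*% net$Q
  m <- (T - 1L) %/% 2L
  S <- C
  Bk <- C
  if (m >= 2) {
    for (k in seq_len(m - 1L)) {
      Bk <- M %*% Bk %*% t(M)
      S <- S + Bk
    }
  }
  list(post_pre = S %*% t(net$Q), pre_post = M %*% (S %*% t(net$Q)),
       QS = net$Q %*% S, M = M, S = S)
}

#' Expected bottom-up plasticity update
#'
#' Presentation-averaged weight change for the bottom-up matrix `Q` when it
#' is the plastic one (lower-layer units pre-synaptic, higher-layer units
#' post-synaptic): the pre-before-post side averages to `Q S` and the
#' post-before-pre side to `Q S t(M)`, so the classical orientation gives
#' `mu (Q S - alpha Q S t(M))`, which vanishes when `t(M) = I/alpha`, and
#' the reverse orientation gives `mu (Q S t(M) - alpha Q S)`. The stability
#' roles of the two orientations are exactly swapped relative to top-down
#' training.
#'
#' @inheritParams expected_stdp_delta
#' @return The expected `Delta Q` matrix (`n_higher` x `n_lower`).
#' @export
expected_stdp_delta_bottom_up <- function(net, C, rule, T = 9L) {
  sums <- expected_pair_sums(net, C, T)
  pre_post_Q <- sums$QS
  post_pre_Q <- sums$QS %*% t(sums$M)
  if (rule$orientation == "classical") {
    rule$mu * (pre_post_Q - rule$alpha * post_pre_Q)
  } else {
    rule$mu * (post_pre_Q - rule$alpha * pre_post_Q)
  }
}

#' Predicted fixed point of the top-down weights
#'
#' For invertible `Q`, the expected plasticity update vanishes when all
#' eigenvalues of `W Q` equal `1/alpha` (reverse orientation) or `alpha`
#' (classical orientation); the corresponding weight configuration is the
#' scaled inverse `W* = Q^{-1}/alpha` or `W* = alpha Q^{-1}`.
#'
#' @param Q Bottom-up weight matrix (square, invertible).
#' @param rule A [linear_rule].
#' @param max_condition Condition-number limit beyond which `Q` is treated
#'   as singular.
#' @return The fixed-point matrix `W*`.
#' @export
predicted_fixed_point <- function(Q, rule, max_condition = 1e12) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  kp <- kappa(Q, exact = TRUE)
  if (!is.finite(kp) || kp > max_condition) {
    stop("predicted_fixed_point: Q is singular or ill-conditioned (condition number ",
         format(kp, digits = 4), ")")
  }
  Qinv <- solve(Q)
  if (rule$orientation == "reverse") Qinv / rule$alpha else rule$alpha * Qinv
}

#' Loop-gain spectrum of the reciprocal circuit
#'
#' Eigenvalues of `W Q`, the matrix that maps lower-layer activity through a
#' full up-and-down traversal of the network. Any eigenvalue with modulus
#' above one marks a strong loop: a pattern of activity amplified on every
#' round trip.
#'
#' @param Q Bottom-up weight matrix.
#' @param W Top-down weight matrix.
#' @return A list with `values` (complex eigenvalues of `W Q`),
#'   `max_modulus`, and `strong_loop` (`TRUE` if `max_modulus > 1`).
#' @export
loop_gain_spectrum <- function(Q, W) {
  stopifnot(ncol(W) == nrow(Q), ncol(Q) == nrow(W))
  ev <- eigen(W %*% Q, only.values = TRUE)$values
  mm <- max(Mod(ev))
  list(values = ev, max_modulus = mm, strong_loop = mm > 1)
}

#' Maximum loop gain
#'
#' Convenience accessor for the maximum modulus eigenvalue of `W Q`.
#' @inheritParams loop_gain_spectrum
#' @return A single non-negative number.
#' @export
max_loop_gain <- function(Q, W) loop_gain_spectrum(Q, W)$max_modulus
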