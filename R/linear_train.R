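#' Stopping criteria for the linear engine
#'
#' @param eigen_limit Any eigenvalue of `W Q` with modulus above this limit
#'   stops the run as `"extreme_weights"`.
#' @param similarity_fraction Run stops as `"weights_too_similar"` when the
#'   standard deviation of `W` falls below this fraction of its initial value.
#' @param window Number of most recent presentations over which slopes and
#'   averages are computed for the convergence test.
#' @param slope_fraction Convergence requires the fitted slopes of both the
#'   weight standard deviation and the per-presentation change norm over the
#'   window to be below this fraction of their window averages.
#' @param small_change_fraction Second convergence clause: the window
#'   average of `||Delta W||` must be below this fraction of `||W||`, so a
#'   run only counts as converged once the residual weight drift is
#'   negligible relative to the weight magnitude.
#' @param max_iterations Presentation cap; reaching it yields
#'   `"did_not_converge"`.
#' @return An object of class `linear_stop_criteria`.
#' @export
linear_stop_criteria <- function(eigen_limit = 1, similarity_fraction = 0.10,
                                 window = 50L, slope_fraction = 0.001,
                                 small_change_fraction = 1e-5,
                                 max_iterations = 20000L) {
  stopifnot(eigen_limit > 0, similarity_fraction > 0, window >= 2,
            slope_fraction > 0, small_change_fraction > 0, max_iterations >= 1)
  structure(list(eigen_limit = eigen_limit,
                 similarity_fraction = similarity_fraction,
                 window = as.integer(window),
                 slope_fraction = slope_fraction,
                 small_change_fraction = small_change_fraction,
                 max_iterations = as.integer(max_iterations)),
            class = "linear_stop_criteria")
}

#' Construct an outcome record
#'
#' @param label One of `"converged"`, `"extreme_weights"`,
#'   `"weights_too_similar"`, `"did_not_converge"`.
#' @param n_stop Presentation count at which the run stopped.
#' @param diagnostics Named list of final diagnostics.
#' @return An object of class `outcome_record`.
#' @export
outcome_record <- function(label, n_stop, diagnostics = list()) {
  label <- match.arg(label, c("converged", "extreme_weights",
                              "weights_too_similar", "did_not_converge"))
  structure(list(label = label, n_stop = as.integer(n_stop),
                 diagnostics = diagnostics),
            class = "outcome_record")
}

#' @export
print.outcome_record <- function(x, ...) {
  cat("Outcome:", x$label, "after", x$n_stop, "presentations\n")
  if (length(x$diagnostics)) {
    for (nm in names(x$diagnostics)) {
      v <- x$diagnostics[[nm]]
      if (is.numeric(v) && length(v) == 1) {
        cat("  ", nm, "=", format(v, digits = 5), "\n")
      }
    }
  }
  invisible(x)
}

slope_over_window <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Classify the state of a linear training run
#'
#' Applies the four stopping rules in priority order at presentation `n`:
#' (1) extreme weights if any eigenvalue of `W Q` has modulus above the
#' limit; (2) weights too similar if `std(W)` has fallen below the similarity
#' fraction of its initial value; (3) converged if, over the trailing window,
#' the slopes of both `std(W)` and `||Delta W||` are below `slope_fraction`
#' of their window averages and the change norm satisfies the small-change
#' clause; (4) did not converge at the presentation cap. Returns `NULL` while
#' no rule fires. The priority order guarantees that a pathological state is
#' never reported as success.
#'
#' @param trace A list with numeric vectors `std_W`, `delta_norm`,
#'   `max_eig` (one entry per presentation so far) and scalars `std_W0`
#'   (initial weight standard deviation), `norm_W` (current `||W||_F`).
#' @param criteria A [linear_stop_criteria].
#' @return An [outcome_record], or `NULL` if no stopping rule applies yet.
#' @export
classify_linear <- function(trace, criteria) {
  n <- length(trace$std_W)
  diag_now <- list(std_W = trace$std_W[n],
                   max_eig = trace$max_eig[n],
                   delta_norm = trace$delta_norm[n])
  if (!is.finite(trace$max_eig[n]) ||
      trace$max_eig[n] > criteria$eigen_limit) {
    return(outcome_record("extreme_weights", n, diag_now))
  }
  if (trace$std_W[n] < criteria$similarity_fraction * trace$std_W0) {
    return(outcome_record("weights_too_similar", n, diag_now))
  }
  w <- criteria$window
  if (n >= w) {
    idx <- (n - w + 1L):n
    s_std <- slope_over_window(trace$std_W[idx])
    s_dn <- slope_over_window(trace$delta_norm[idx])
    m_std <- mean(trace$std_W[idx])
    m_dn <- mean(trace$delta_norm[idx])
    flat <- abs(s_std) < criteria$slope_fraction * m_std &&
      abs(s_dn) < criteria$slope_fraction * max(m_dn, .Machine$double.eps)
    small <- m_dn < criteria$small_change_fraction * trace$norm_W
    if (flat && small) {
      return(outcome_record("converged", n, diag_now))
    }
  }
  if (n >= criteria$max_iterations) {
    return(outcome_record("did_not_converge", n, diag_now))
  }
  NULL
}

#' Train the top-down weights of the linear engine
#'
#' Iterates stimulus presentations, applying the plasticity update after each
#' one and recording per-presentation diagnostics (`||Delta W||`, `std(W)`,
#' maximum loop gain, and the lagged weight correlation `corr(W(N), W(N-100))`),
#' until one of the stopping rules fires. In `"expected"` update mode the
#' deterministic presentation-averaged update is iterated directly on the
#' stimulus cross-correlation matrix `C`; in `"per_stimulus"` mode an input
#' vector with covariance `C` is drawn each presentation and the pairwise
#' update is computed from the realized trajectory.
#'
#' @param net A [linear_network] supplying `Q` and the initial `W`.
#' @param C Stimulus cross-correlation matrix.
#' @param rule A [linear_rule].
#' @param criteria A [linear_stop_criteria].
#' @param T Presentation length in time-points (odd).
#' @param corr_lag Lag, in presentations, for the weight autocorrelation
#'   diagnostic.
#' @param plastic Which weight matrix learns: `"top_down"` (`W`, the
#'   standard case), `"bottom_up"` (`Q`, with `W` held fixed; the pre/post
#'   roles are swapped accordingly), or `"both"` (concurrent plasticity;
#'   requires `concurrent`).
#' @param concurrent A [concurrent_params] giving the relative rate,
#'   orientation and bias of bottom-up learning when `plastic = "both"`.
#' @param homeostasis Optional [homeostasis_params]. Every
#'   `interval` presentations the rows of `W` and the per-neuron input
#'   gains are rescaled towards the target activity level; the lower-layer
#'   "rate" of the linear model is the root-mean-square activity of the
#'   lower units across the presentation's time-points (in expected mode,
#'   computed from the stimulus correlation), so the target is in activity
#'   units rather than spikes/s.
#' @return A list with `net` (final network), `outcome` (an
#'   [outcome_record]), `input_gain`, and `trace` (a data frame of
#'   per-presentation diagnostics: `N`, `std_W`, `delta_norm`, `max_eig`,
#'   `corr_lagged`, `corr_fixed_point`). For `plastic = "bottom_up"` the
#'   `std_W` and correlation diagnostics describe `Q` instead.
#' @export
train_linear <- function(net, C, rule, criteria = linear_stop_criteria(),
                         T = 9L, corr_lag = 100L,
                         plastic = c("top_down", "bottom_up", "both"),
                         concurrent = NULL, homeostasis = NULL) {
  stopifnot(inherits(net, "linear_network"), inherits(rule, "linear_rule"))
  plastic <- match.arg(plastic)
  if (plastic == "both" && is.null(concurrent)) {
    stop("train_linear: plastic = 'both' requires concurrent parameters")
  }
  W <- net$W
  Q <- net$Q
  learned_is_W <- plastic != "bottom_up"
  std_W0 <- sd(if (learned_is_W) as.vector(W) else as.vector(Q))
  target <- fixed_point_for(plastic, Q, W, rule)
  Csqrt <- if (rule$update_mode == "per_stimulus") sym_sqrt(C) else NULL
  input_gain <- rep(1, net$n_lower)
  m_half <- (T - 1L) %/% 2L
  rule_Q <- if (plastic == "both") {
    linear_rule(concurrent$orientation, alpha = concurrent$alpha,
                mu = abs(concurrent$zeta) * rule$mu,
                update_mode = rule$update_mode,
                multiplicative = rule$multiplicative, W_max = rule$W_max)
  } else if (plastic == "bottom_up") rule
  std_W <- numeric(0); delta_norm <- numeric(0); max_eig <- numeric(0)
  corr_lagged <- numeric(0); corr_fp <- numeric(0)
  hist <- list()
  outcome <- NULL
  n <- 0L
  while (is.null(outcome)) {
    n <- n + 1L
    netn <- linear_network(Q, W)
    Ceff <- if (any(input_gain != 1)) {
      C * outer(input_gain, input_gain)
    } else C
    if (rule$update_mode == "expected") {
      sums <- expected_pair_sums(netn, Ceff, T)
      act_rms <- sqrt(pmax(diag(sums$S + sums$M %*% Ceff %*% t(sums$M)), 0) /
                        (m_half + 1))
    } else {
      x <- input_gain * as.vector(Csqrt %*% rnorm(netn$n_lower))
      traj <- simulate_presentation_linear(netn, x, T)
      sums <- linear_pair_sums(traj)
      act_rms <- sqrt(rowMeans(traj$L^2))
    }
    dW <- NULL; dQ <- NULL
    if (learned_is_W) {
      dW <- compose_linear_delta(rule, sums$pre_post, sums$post_pre, W)
    }
    if (plastic != "top_down") {
      rq <- if (plastic == "both") rule_Q else rule
      if (rule$update_mode == "expected") {
        pre_post_Q <- sums$QS
        post_pre_Q <- sums$QS %*% t(sums$M)
      } else {
        pre_post_Q <- t(sums$post_pre)
        post_pre_Q <- t(sums$pre_post)
      }
      dQ <- compose_linear_delta(rq, pre_post_Q, post_pre_Q, Q, rate = rq$mu)
    }
    if (!is.null(dW)) W <- W + dW
    if (!is.null(dQ)) Q <- Q + dQ
    if (!is.null(homeostasis) && n %% homeostasis$interval == 0L) {
      hs <- homeostatic_rescale(W, input_gain, act_rms, homeostasis)
      W <- hs$W; input_gain <- hs$input_gain
    }
    learned <- if (learned_is_W) W else Q
    d_used <- if (learned_is_W) dW else dQ
    hist[[n]] <- learned
    std_W[n] <- sd(as.vector(learned))
    delta_norm[n] <- sqrt(sum(d_used^2))
    max_eig[n] <- if (all(is.finite(W)) && all(is.finite(Q))) {
      max_loop_gain(Q, W)
    } else Inf
    corr_lagged[n] <- if (n > corr_lag) {
      cor(as.vector(learned), as.vector(hist[[n - corr_lag]]))
    } else NA_real_
    corr_fp[n] <- if (!is.null(target)) {
      cor(as.vector(learned), as.vector(target))
    } else NA_real_
    if (n > corr_lag + 1L) hist[n - corr_lag - 1L] <- list(NULL)
    outcome <- classify_linear(
      list(std_W = std_W, delta_norm = delta_norm, max_eig = max_eig,
           std_W0 = std_W0, norm_W = sqrt(sum(learned^2))),
      criteria)
  }
  outcome$diagnostics$corr_fixed_point <- corr_fp[n]
  outcome$diagnostics$std_W0 <- std_W0
  trace <- data.frame(N = seq_len(n), std_W = std_W,
                      delta_norm = delta_norm, max_eig = max_eig,
                      corr_lagged = corr_lagged, corr_fixed_point = corr_fp)
  list(net = linear_network(Q, W), outcome = outcome,
       input_gain = input_gain, trace = trace)
}

# Predicted fixed point of the learned matrix, when the fixed counterpart
# is invertible: W* = Q^-1/alpha (reverse) or alpha Q^-1 (classical) for
# top-down learning; Q* = W^-1/alpha (classical) or alpha W^-1 (reverse)
# for bottom-up learning (the orientation roles swap with the synapse).
fixed_point_for <- function(plastic, Q, W, rule) {
  tryCatch({
    if (plastic != "bottom_up") {
      predicted_fixed_point(Q, rule)
    } else {
      if (nrow(W) != ncol(W)) stop("W not square")
      Winv <- solve(W)
      if (rule$orientation == "classical") Winv / rule$alpha
      else rule$alpha * Winv
    }
  }, error = function(e) NULL)
}

#' Draw an initial top-down weight matrix
#'
#' Entries are independent normal draws with mean zero and the given
#' standard deviation.
#'
#' @param n_lower,n_higher Layer sizes.
#' @param sd Standard deviation of the initial weights.
#' @return An `n_lower` by `n_higher` matrix.
#' @export
initial_top_down_matrix <- function(n_lower, n_higher, sd = 0.003) {
  matrix(rnorm(n_lower * n_higher, sd = sd), n_lower, n_higher)
}
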