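# Uncentered (cosine) similarity between two weight snapshots.  Centring by
# the mean (Pearson) degenerates when the weights have collapsed to a
# single value: the residual is pure sampling noise and the correlation
# never certifies stability, making the weights-too-similar outcome
# unreachable.  The uncentered form agrees with Pearson whenever the weight
# spread dominates the mean (all diverse converged runs) and approaches 1
# for collapsed weights, where stability is carried by the common level.
weight_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Classify the state of a spiking training run
#'
#' Applies the stopping rules on the stride grid of logged weight snapshots,
#' in priority order: (1) `"extreme_weights"` when more than the configured
#' fraction of weights lies within the margin of the bounds `-W_max` or
#' `W_max` (or when the run was flagged pathological); (2) once the lagged
#' weight similarity (uncentered correlation of the vectorized snapshots)
#' exceeds its threshold *and* the weight standard deviation is stable
#' over the longer lag (relative change below `std_change_fraction`, or
#' absolute slope below `std_slope_abs` - either suffices), the weights
#' are deemed stabilized and the run is classified by diversity:
#' `"weights_too_similar"` if the standard deviation is below the
#' diversity threshold, `"converged"` otherwise; (3) `"did_not_converge"`
#' at the presentation cap. Returns `NULL` while no rule fires.
#'
#' @param history List of weight-matrix snapshots, snapshot `k` taken at
#'   presentation `k * stride`. Only the trailing `std_lag / stride + 1`
#'   snapshots are required; earlier entries may be `NULL`.
#' @param criteria A [spiking_stop_criteria].
#' @param w_max The weight bound of the rule in force.
#' @param stride Snapshot stride in presentations; must divide both lags.
#' @param pathological Set `TRUE` when the membrane dynamics overflowed.
#' @return An [outcome_record], or `NULL`.
#' @export
classify_spiking <- function(history, criteria, w_max, stride = 100L,
                             pathological = FALSE) {
  stopifnot(inherits(criteria, "spiking_stop_criteria"),
            criteria$corr_lag %% stride == 0, criteria$std_lag %% stride == 0)
  n <- length(history)
  N <- n * stride
  W <- history[[n]]
  std_now <- sd(as.vector(W))
  diag_now <- list(std_W = std_now, pathological = pathological)
  at_bound <- mean(abs(W) >= w_max - criteria$extreme_margin)
  diag_now$fraction_at_bounds <- at_bound
  if (pathological || at_bound > criteria$extreme_fraction) {
    return(outcome_record("extreme_weights", N, diag_now))
  }
  k3 <- criteria$corr_lag %/% stride
  k6 <- criteria$std_lag %/% stride
  if (n > k6 && !is.null(history[[n - k3]]) && !is.null(history[[n - k6]])) {
    cl <- weight_similarity(as.vector(W), as.vector(history[[n - k3]]))
    std_then <- sd(as.vector(history[[n - k6]]))
    diag_now$corr_lagged <- cl
    d_std <- abs(std_now - std_then)
    std_stable <- d_std < criteria$std_change_fraction * std_now ||
      d_std / criteria$std_lag < criteria$std_slope_abs
    if (is.finite(cl) && cl > criteria$corr_thresh && std_stable) {
      label <- if (std_now < criteria$diversity_std_thresh) {
        "weights_too_similar"
      } else "converged"
      return(outcome_record(label, N, diag_now))
    }
  }
  if (N >= criteria$max_presentations) {
    return(outcome_record("did_not_converge", N, diag_now))
  }
  NULL
}

#' Draw the initial top-down weights of the spiking engine
#'
#' Entries uniform in `[-0.05, 0.05]`.
#'
#' @param n_lower,n_higher Layer sizes.
#' @return An `n_lower` by `n_higher` matrix.
#' @export
initial_spiking_weights <- function(n_lower, n_higher) {
  matrix(runif(n_lower * n_higher, -0.05, 0.05), n_lower, n_higher)
}

#' Train the top-down weights of the integrate-and-fire network
#'
#' Runs the full training loop: each presentation draws a correlated input
#' strength vector, simulates the spiking dynamics, accumulates the pairwise
#' STDP update, applies it with clipping, and (optionally) applies the
#' homeostatic, concurrent bottom-up, or higher-layer-drive rule variants.
#' Weight snapshots are logged every `stride` presentations and the
#' four-way outcome classification is evaluated on that grid. The run is
#' deterministic given the R random seed in force at the call.
#'
#' @param Q Bottom-up weight matrix (fixed unless `concurrent` is given).
#' @param lif A [lif_config].
#' @param ensemble A [stimulus_ensemble].
#' @param rule A [spiking_rule].
#' @param criteria A [spiking_stop_criteria].
#' @param stride Diagnostics/classification stride, presentations.
#' @param homeostasis Optional [homeostasis_params].
#' @param concurrent Optional [concurrent_params] enabling bottom-up
#'   plasticity.
#' @param higher_input Optional [higher_input_params] adding external drive
#'   to the higher layer.
#' @param W0 Initial top-down weights; default uniform in `[-0.05, 0.05]`.
#' @return A list with `W` (final top-down weights), `Q` (final bottom-up
#'   weights), `outcome` (an [outcome_record]), `input_gain`, and `trace`
#'   (data frame on the stride grid: `N`, `std_W`, `corr_lagged`,
#'   `rate_lower`, `rate_higher`, `fraction_at_bounds`).
#' @export
train_spiking <- function(Q, lif, ensemble, rule,
                          criteria = spiking_stop_criteria(),
                          stride = 100L, homeostasis = NULL,
                          concurrent = NULL, higher_input = NULL,
                          W0 = NULL) {
  stopifnot(inherits(lif, "lif_config"), inherits(ensemble, "stimulus_ensemble"),
            inherits(rule, "spiking_rule"),
            inherits(criteria, "spiking_stop_criteria"),
            nrow(Q) == lif$n_higher, ncol(Q) == lif$n_lower)
  n_lower <- lif$n_lower; n_higher <- lif$n_higher
  if (is.null(W0)) W0 <- initial_spiking_weights(n_lower, n_higher)
  W <- W0
  input_gain <- rep(1, n_lower)
  envelope <- input_time_course(seq(0, ensemble$presentation_ms - lif$dt,
                                    by = lif$dt), ensemble)
  Csqrt <- sym_sqrt(ensemble$C_input)  # cached colouring factor
  rate_sd <- ensemble$J_mean / 4
  keep <- criteria$std_lag %/% stride + 1L  # trailing snapshots needed
  history <- list()
  tN <- integer(0); t_std <- numeric(0); t_corr <- numeric(0)
  t_rl <- numeric(0); t_rh <- numeric(0); t_fb <- numeric(0)
  rate_sum <- 0
  homeo_rates <- rep(0, n_lower)
  outcome <- NULL
  n <- 0L
  rl_last <- NA_real_; rh_last <- NA_real_
  while (is.null(outcome)) {
    n <- n + 1L
    Jbar <- input_gain *
      pmax(ensemble$J_mean + rate_sd * as.vector(Csqrt %*% rnorm(n_lower)), 0)
    JbarH <- if (!is.null(higher_input)) {
      higher_layer_drive(higher_input, ensemble)
    } else NULL
    rec <- run_presentation_spiking(W, Q, lif, ensemble, Jbar,
                                    Jbar_higher = JbarH, envelope = envelope)
    if (rec$pathological) {
      outcome <- outcome_record("extreme_weights", n,
                                list(pathological = TRUE,
                                     std_W = sd(as.vector(W))))
      break
    }
    sums <- cpp_stdp_pair_sums(rec$lower_spikes, rec$higher_spikes,
                               rule$tau_stdp)
    W <- pmin(pmax(W + stdp_compose_delta(rule, sums, W), -rule$W_max),
              rule$W_max)
    if (!is.null(concurrent)) {
      Q <- concurrent_bottom_up_update(Q, concurrent, rule, rec)
    }
    rl_last <- rec$rate_lower; rh_last <- rec$rate_higher
    if (!is.null(homeostasis)) {
      homeo_rates <- homeo_rates +
        rowSums(rec$lower_spikes) / (ensemble$presentation_ms / 1000)
      if (n %% homeostasis$interval == 0L) {
        hs <- homeostatic_rescale(W, input_gain,
                                  homeo_rates / homeostasis$interval,
                                  homeostasis)
        W <- hs$W; input_gain <- hs$input_gain
        homeo_rates <- rep(0, n_lower)
      }
    }
    if (n %% stride == 0L) {
      k <- n %/% stride
      history[[k]] <- W
      if (k > keep) history[k - keep] <- list(NULL)  # free old snapshots
      outcome <- classify_spiking(history, criteria, rule$W_max, stride)
      tN <- c(tN, n)
      t_std <- c(t_std, sd(as.vector(W)))
      t_corr <- c(t_corr, {
        k3 <- criteria$corr_lag %/% stride
        if (k > k3 && !is.null(history[[k - k3]])) {
          weight_similarity(as.vector(W), as.vector(history[[k - k3]]))
        } else NA_real_
      })
      t_rl <- c(t_rl, rl_last); t_rh <- c(t_rh, rh_last)
      t_fb <- c(t_fb, mean(abs(W) >= rule$W_max - criteria$extreme_margin))
    }
  }
  trace <- data.frame(N = tN, std_W = t_std, corr_lagged = t_corr,
                      rate_lower = t_rl, rate_higher = t_rh,
                      fraction_at_bounds = t_fb)
  list(W = W, Q = Q, outcome = outcome, input_gain = input_gain,
       trace = trace)
}
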