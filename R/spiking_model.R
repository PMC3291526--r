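#' Simulate one stimulus presentation of the integrate-and-fire network
#'
#' Integrates the conductance-based leaky integrate-and-fire dynamics of
#' both layers over one presentation with forward-Euler steps of `dt`.
#' Lower-layer neurons receive rate-coded external stimulus input (mean
#' `Jbar[i] * envelope(t)`, Gaussian per time-step, rectified at zero),
#' excitatory Gaussian noise, and delayed top-down spike input through `W`;
#' higher-layer neurons receive delayed bottom-up spike input through `Q`,
#' the same noise process, and optionally their own external drive. A
#' neuron's conductance decays with `tau_syn`, accumulates increments of
#' `g_gain` per input spike (weighted by the synaptic weight for inter-layer
#' input), and is reset to zero when the neuron itself fires, so it tracks
#' the input received since the last action potential. Negative top-down
#' weights contribute negative conductance, which hyperpolarizes.
#'
#' @param W Top-down weight matrix (`n_lower` x `n_higher`).
#' @param Q Bottom-up weight matrix (`n_higher` x `n_lower`).
#' @param lif A [lif_config].
#' @param ensemble A [stimulus_ensemble].
#' @param Jbar Per-neuron mean external input rates for this presentation
#'   (spikes/s), e.g. from [sample_input_strengths].
#' @param Jbar_higher Optional external input rates for the higher layer
#'   (spikes/s), or `NULL`.
#' @param envelope Optional replacement for the standard temporal envelope
#'   (numeric vector, one value per time-step); used e.g. by the
#'   reconstruction probe, which zeroes the input after 50 ms.
#' @param g_clamp If non-negative, every conductance is frozen at this value
#'   (diagnostic mode exposing the bare membrane equation).
#' @param record_V If `TRUE`, the lower-layer membrane potential trace is
#'   returned.
#' @return A list of class `spike_presentation` with integer spike rasters
#'   `lower_spikes`, `higher_spikes` (neurons x time-steps), mean layer
#'   rates `rate_lower`, `rate_higher` (spikes/s), and a `pathological`
#'   flag set when the membrane potential left the finite range.
#' @export
run_presentation_spiking <- function(W, Q, lif, ensemble, Jbar,
                                     Jbar_higher = NULL, envelope = NULL,
                                     g_clamp = -1, record_V = FALSE) {
  stopifnot(inherits(lif, "lif_config"), inherits(ensemble, "stimulus_ensemble"),
            nrow(W) == ncol(Q), ncol(W) == nrow(Q), length(Jbar) == nrow(W))
  if (is.null(envelope)) {
    envelope <- input_time_course(seq(0, ensemble$presentation_ms - lif$dt,
                                      by = lif$dt), ensemble)
  }
  rec <- cpp_run_presentation(Q, W, lif$tau_m, lif$V_rest, lif$E_exc,
                              lif$V_thresh, lif$V_reset, lif$g_gain,
                              lif$tau_syn, lif$dt, Jbar, envelope,
                              ensemble$sigma_input, lif$noise_S,
                              lif$sigma_noise, as.integer(lif$delay / lif$dt),
                              Jbar_higher, g_clamp, record_V,
                              lif$coupling_gain)
  class(rec) <- "spike_presentation"
  rec
}

#' Apply the pairwise STDP update from one presentation
#'
#' Accumulates, over every pair of one higher-layer (pre-synaptic) and one
#' lower-layer (post-synaptic) spike within the presentation, an exponential
#' window contribution `exp(-|dt|/tau_stdp)`: `A_plus` on the potentiating
#' side and `-alpha * A_plus` on the depressing side. For the classical
#' orientation pre-before-post pairs potentiate; for the reverse orientation
#' post-before-pre pairs potentiate. The accumulated change is applied at
#' the end of the presentation and the result clipped to
#' `[-W_max, W_max]`. With `rule$multiplicative`, the potentiating
#' accumulation is first scaled entry-wise by `(W_max - w)` and the
#' depressing one by `|w|`.
#'
#' @param rule A [spiking_rule].
#' @param record A `spike_presentation` from [run_presentation_spiking].
#' @param W Current top-down weight matrix.
#' @return The updated, clipped weight matrix.
#' @export
stdp_weight_update <- function(rule, record, W) {
  stopifnot(inherits(rule, "spiking_rule"))
  sums <- cpp_stdp_pair_sums(record$lower_spikes, record$higher_spikes,
                             rule$tau_stdp)
  dW <- stdp_compose_delta(rule, sums, W)
  pmin(pmax(W + dW, -rule$W_max), rule$W_max)
}

# Combine potentiating/depressing pair sums into a weight change, honouring
# orientation, depression bias and the optional multiplicative soft bound.
stdp_compose_delta <- function(rule, sums, W) {
  if (rule$orientation == "classical") {
    pot <- sums$pre_post; dep <- sums$post_pre
  } else {
    pot <- sums$post_pre; dep <- sums$pre_post
  }
  if (rule$multiplicative) {
    f <- multiplicative_stdp_factors(W, rule$W_max)
    rule$A_plus * (pot * f$pot_factor - rule$alpha * dep * f$dep_factor)
  } else {
    rule$A_plus * (pot - rule$alpha * dep)
  }
}

#' Exact all-pairs exponential-window STDP pair sums
#'
#' For every ordered pair of one higher-layer and one lower-layer spike
#' within a presentation, accumulates `exp(-|lag|/tau_stdp)` into
#' `pre_post` (higher spike strictly earlier) or `post_pre` (lower spike
#' strictly earlier); spikes in the same time bin have no temporal order
#' and are excluded. Computed with per-neuron exponential traces, which is
#' exact for the all-pairs rule.
#'
#' @param lower_spikes,higher_spikes Integer 0/1 spike rasters
#'   (neurons x time-steps).
#' @param tau_stdp STDP window time constant (in time-steps).
#' @return A list with matrices `pre_post` and `post_pre`
#'   (`n_lower` x `n_higher`).
#' @export
stdp_pair_sums <- function(lower_spikes, higher_spikes, tau_stdp) {
  cpp_stdp_pair_sums(lower_spikes, higher_spikes, tau_stdp)
}

#' Steady-state membrane potential under a clamped conductance
#'
#' Fixed point of the membrane equation when the conductance is held
#' constant: `V = (V_rest + g * E_exc) / (1 + g)`.
#'
#' @param g Conductance (dimensionless).
#' @param lif A [lif_config].
#' @return The steady-state potential (mV).
#' @export
lif_steady_state <- function(g, lif) {
  (lif$V_rest + g * lif$E_exc) / (1 + g)
}
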