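#' Homeostatic synaptic scaling parameters
#'
#' @param target_rate Target firing rate `F` for lower-layer neurons
#'   (spikes/s).
#' @param strength Relative strength of the homeostatic mechanism (the
#'   Table-style values 0.1, 1, 10, 100 are typical).
#' @param interval Number of presentations between scaling applications.
#' @param gain_per_strength Conversion from the relative strength to the
#'   linear restoring gain (see [homeostatic_rescale]).
#' @param clip Two-sided limits on a single scaling factor application.
#' @return An object of class `homeostasis_params`.
#' @export
homeostasis_params <- function(target_rate = 80, strength = 1,
                               interval = 30L, gain_per_strength = 0.01,
                               clip = c(0.5, 2)) {
  stopifnot(target_rate > 0, strength >= 0, interval >= 1,
            gain_per_strength > 0, length(clip) == 2, clip[1] > 0,
            clip[1] <= 1, clip[2] >= 1)
  structure(list(target_rate = target_rate, strength = strength,
                 interval = as.integer(interval),
                 gain_per_strength = gain_per_strength, clip = clip),
            class = "homeostasis_params")
}

#' Homeostatic rescaling of all inputs to the lower-layer neurons
#'
#' Multiplies row `i` of the top-down weight matrix and neuron `i`'s future
#' external-input gain by a factor `f_i = 1 + eta * (F - r_i) / F`, clipped
#' to the configured range, where `r_i` is the neuron's mean firing rate over
#' the last scaling interval, `F` the target rate, and
#' `eta = strength * gain_per_strength` the effective restoring gain. The
#' factor equals 1 at the set-point and strictly reduces the total input
#' gain of a neuron firing above target (and increases it below target); the
#' clip guards against single-step blow-up at large strengths and against
#' the degenerate zero-rate case.
#'
#' @param W Top-down weight matrix (`n_lower` x `n_higher`).
#' @param input_gain Per-lower-neuron multiplicative gain applied to future
#'   external input.
#' @param mean_rates Per-lower-neuron mean firing rate over the last
#'   interval (spikes/s).
#' @param params A [homeostasis_params].
#' @return A list with the rescaled `W`, updated `input_gain`, and the
#'   applied `factors`.
#' @export
homeostatic_rescale <- function(W, input_gain, mean_rates, params) {
  stopifnot(inherits(params, "homeostasis_params"),
            nrow(W) == length(input_gain), length(mean_rates) == nrow(W))
  eta <- params$strength * params$gain_per_strength
  f <- 1 + eta * (params$target_rate - mean_rates) / params$target_rate
  f <- pmin(pmax(f, params$clip[1]), params$clip[2])
  list(W = W * f, input_gain = input_gain * f, factors = f)
}

#' Soft-bound factors of the multiplicative STDP rule
#'
#' Potentiation is scaled by the distance of the current weight from the
#' maximum weight, `(W_max - w)/W_max`, and depression by the distance of
#' the current weight from zero, `|w|/W_max` (applied on the signed axis,
#' so negative weights are depressed towards zero as well). Both distances
#' are normalized by `W_max`, so a weight in the middle of its range
#' changes at about the amplitude of the weight-independent rule.
#' Potentiation vanishes at the ceiling and depression at the floor,
#' producing a quadratic update map whose attracting fixed points sit near
#' zero and near `W_max`.
#'
#' @param w Current weight(s); vectorized.
#' @param W_max Maximum weight.
#' @return A list with `pot_factor` and `dep_factor`, same shape as `w`.
#' @export
multiplicative_stdp_factors <- function(w, W_max) {
  list(pot_factor = (W_max - w) / W_max, dep_factor = abs(w) / W_max)
}

#' Concurrent bottom-up plasticity parameters
#'
#' @param zeta Learning rate of bottom-up plasticity relative to the
#'   top-down rule; a negative sign selects the reverse orientation for the
#'   bottom-up rule when `orientation` is not given explicitly.
#' @param alpha Depression/potentiation bias of the bottom-up rule.
#' @param orientation Orientation of the bottom-up rule, or `NULL` to
#'   derive it from the sign of `zeta` (negative = reverse).
#' @return An object of class `concurrent_params`.
#' @export
concurrent_params <- function(zeta = 1, alpha = 1.2, orientation = NULL) {
  stopifnot(zeta != 0, alpha > 0)
  if (is.null(orientation)) {
    orientation <- if (zeta < 0) "reverse" else "classical"
  }
  orientation <- match.arg(orientation, c("classical", "reverse"))
  structure(list(zeta = zeta, alpha = alpha, orientation = orientation),
            class = "concurrent_params")
}

#' Concurrent update of the bottom-up weights (spiking engine)
#'
#' Applies the pairwise exponential-window rule to the bottom-up matrix `Q`
#' using the same presentation record as the top-down update, with the roles
#' reversed: the lower-layer neuron is pre-synaptic and the higher-layer
#' neuron post-synaptic. The learning rate is `|zeta|` times the top-down
#' amplitude, with the bottom-up orientation and bias taken from `params`.
#' `Q` is clipped to the same magnitude bound as `W`.
#'
#' @param Q Bottom-up weight matrix (`n_higher` x `n_lower`).
#' @param params A [concurrent_params].
#' @param rule The top-down [spiking_rule] (supplies `A_plus`, `tau_stdp`,
#'   `W_max`).
#' @param record A `spike_presentation`.
#' @return The updated, clipped bottom-up matrix.
#' @export
concurrent_bottom_up_update <- function(Q, params, rule, record) {
  stopifnot(inherits(params, "concurrent_params"), inherits(rule, "spiking_rule"))
  sums <- cpp_stdp_pair_sums(record$lower_spikes, record$higher_spikes,
                             rule$tau_stdp)
  # from Q's viewpoint: lower spike before higher spike is pre-before-post
  pre_post_Q <- t(sums$post_pre)
  post_pre_Q <- t(sums$pre_post)
  if (params$orientation == "classical") {
    pot <- pre_post_Q; dep <- post_pre_Q
  } else {
    pot <- post_pre_Q; dep <- pre_post_Q
  }
  dQ <- abs(params$zeta) * rule$A_plus * (pot - params$alpha * dep)
  pmin(pmax(Q + dQ, -rule$W_max), rule$W_max)
}

#' Higher-layer external drive parameters
#'
#' @param C_higher Cross-correlation matrix for the higher-layer external
#'   inputs (distinct from the lower-layer one).
#' @param strength_ratio Ratio of higher-layer to lower-layer external input
#'   strength.
#' @return An object of class `higher_input_params`.
#' @export
higher_input_params <- function(C_higher, strength_ratio = 1) {
  stopifnot(is.matrix(C_higher), nrow(C_higher) == ncol(C_higher),
            strength_ratio >= 0)
  structure(list(C_higher = C_higher, strength_ratio = strength_ratio),
            class = "higher_input_params")
}

#' Sample the higher-layer external input strengths for one presentation
#'
#' Draws a correlated rate vector for the higher-layer neurons in the same
#' way as the lower-layer stimulus ([sample_input_strengths]) but on
#' `C_higher`, scaled by the strength ratio. The same temporal envelope is
#' applied inside the presentation loop. A ratio of zero recovers the
#' standard model in which higher-layer neurons receive no external
#' stimulus.
#'
#' @param params A [higher_input_params].
#' @param ensemble The lower-layer [stimulus_ensemble] (supplies the base
#'   strength).
#' @return A vector of non-negative rates (spikes/s), or `NULL` when the
#'   ratio is zero.
#' @export
higher_layer_drive <- function(params, ensemble) {
  stopifnot(inherits(params, "higher_input_params"),
            inherits(ensemble, "stimulus_ensemble"))
  if (params$strength_ratio == 0) return(NULL)
  m <- ensemble$J_mean * params$strength_ratio
  sample_input_strengths(params$C_higher, J_mean = m, rate_sd = m / 4)
}
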