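#' Leaky integrate-and-fire neuron and network constants
#'
#' Membrane, synapse and noise constants of the conductance-based
#' integrate-and-fire engine. All voltages are in mV, times in ms,
#' rates in spikes/s.
#'
#' @param tau_m Membrane time constant (ms).
#' @param V_rest Resting potential (mV).
#' @param E_exc Excitatory reversal potential (mV).
#' @param V_thresh Spike threshold (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param g_gain Dimensionless conductance increment per input spike.
#' @param tau_syn Synaptic (conductance decay) time constant (ms).
#' @param delay Inter-layer synaptic transmission delay (ms); must be a
#'   multiple of `dt`.
#' @param noise_S Mean rate of the excitatory noise process (spikes/s).
#' @param sigma_noise Noise standard deviation as a fraction of `noise_S`.
#' @param dt Integration time-step (ms).
#' @param n_lower,n_higher Layer sizes.
#' @param coupling_gain Scale factor on the inter-layer (bottom-up and
#'   top-down) conductance increments. The reference network has 100
#'   neurons per layer; when a layer is scaled down to `n` neurons, setting
#'   `coupling_gain = 100 / n` preserves the aggregate synaptic drive each
#'   neuron receives from the other layer, keeping the operating point of
#'   the full-size network. Defaults to 1 (no compensation).
#' @return An object of class `lif_config`.
#' @export
lif_config <- function(tau_m = 10, V_rest = -74, E_exc = 0, V_thresh = -18,
                       V_reset = -60, g_gain = 0.04, tau_syn = 15, delay = 15,
                       noise_S = 2000, sigma_noise = 0.5, dt = 1,
                       n_lower = 100L, n_higher = 100L, coupling_gain = 1) {
  stopifnot(V_reset < V_thresh, tau_m > 0, tau_syn > 0, dt > 0,
            delay > 0, delay %% dt == 0, g_gain > 0, noise_S >= 0,
            sigma_noise >= 0, n_lower >= 1, n_higher >= 1, coupling_gain > 0)
  structure(list(tau_m = tau_m, V_rest = V_rest, E_exc = E_exc,
                 V_thresh = V_thresh, V_reset = V_reset, g_gain = g_gain,
                 tau_syn = tau_syn, delay = as.integer(delay),
                 noise_S = noise_S, sigma_noise = sigma_noise, dt = dt,
                 n_lower = as.integer(n_lower),
                 n_higher = as.integer(n_higher),
                 coupling_gain = coupling_gain),
            class = "lif_config")
}

#' External stimulus ensemble for the spiking engine
#'
#' Describes the correlated Gaussian input rates delivered to the lower layer
#' and their temporal envelope within a presentation: a Gaussian transient of
#' height 1 centred at 30 ms with width 20 ms during the first 80 ms,
#' followed by a sustained tonic level at 1/5 of the peak for a further
#' 80 ms (160 ms per presentation in total).
#'
#' @param C_input Input cross-correlation matrix (`n_lower` square, PSD,
#'   unit diagonal), e.g. from [build_input_correlation].
#' @param J_mean Mean external input rate (spikes/s).
#' @param sigma_input Within-presentation input standard deviation as a
#'   fraction of the instantaneous mean rate.
#' @param gauss_center,gauss_width Centre and width (standard deviation) of
#'   the transient Gaussian envelope (ms).
#' @param gauss_height Peak envelope value.
#' @param tonic_level Envelope value during the tonic phase (1/5 of the peak).
#' @param transient_ms Duration of the transient phase (ms).
#' @param tonic_extra_ms Duration of the tonic phase (ms).
#' @return An object of class `stimulus_ensemble`.
#' @export
stimulus_ensemble <- function(C_input, J_mean = 20000, sigma_input = 1.0,
                              gauss_center = 30, gauss_width = 20,
                              gauss_height = 1, tonic_level = gauss_height / 5,
                              transient_ms = 80, tonic_extra_ms = 80) {
  stopifnot(is.matrix(C_input), nrow(C_input) == ncol(C_input),
            J_mean > 0, sigma_input >= 0, gauss_height > 0,
            tonic_level >= 0, transient_ms > 0, tonic_extra_ms >= 0)
  structure(list(C_input = C_input, J_mean = J_mean,
                 sigma_input = sigma_input, gauss_center = gauss_center,
                 gauss_width = gauss_width, gauss_height = gauss_height,
                 tonic_level = tonic_level, transient_ms = transient_ms,
                 tonic_extra_ms = tonic_extra_ms,
                 presentation_ms = transient_ms + tonic_extra_ms),
            class = "stimulus_ensemble")
}

#' Temporal envelope of the external input
#'
#' Gaussian transient during the initial phase of a presentation, sustained
#' tonic level afterwards, zero outside the presentation.
#'
#' @param t_ms Time (ms) from presentation onset; vectorized.
#' @param ensemble A [stimulus_ensemble].
#' @return Envelope values in `[0, gauss_height]`.
#' @examples
#' ens <- stimulus_ensemble(diag(2))
#' input_time_course(30, ens)   # 1, the transient peak
#' input_time_course(120, ens)  # 0.2, the tonic level
#' input_time_course(200, ens)  # 0, outside the presentation
#' @export
input_time_course <- function(t_ms, ensemble) {
  out <- numeric(length(t_ms))
  transient <- t_ms >= 0 & t_ms < ensemble$transient_ms
  tonic <- t_ms >= ensemble$transient_ms & t_ms < ensemble$presentation_ms
  out[transient] <- ensemble$gauss_height *
    exp(-(t_ms[transient] - ensemble$gauss_center)^2 /
          (2 * ensemble$gauss_width^2))
  out[tonic] <- ensemble$tonic_level
  out
}

#' Exponential-window STDP rule for the spiking engine
#'
#' @param orientation `"classical"` (pre-before-post potentiates) or
#'   `"reverse"` (post-before-pre potentiates). At a top-down synapse the
#'   higher-layer neuron is pre-synaptic.
#' @param alpha Depression/potentiation amplitude ratio; the depressing side
#'   has amplitude `alpha * A_plus`.
#' @param A_plus Potentiation amplitude per spike pair.
#' @param tau_stdp STDP window time constant (ms).
#' @param W_max Hard weight bound; weights are clipped to
#'   `[-W_max, W_max]` after each presentation.
#' @param multiplicative If `TRUE`, use the soft-bound multiplicative rule:
#'   potentiation is scaled entry-wise by `(W_max - w)` and depression by
#'   `|w|` (see [multiplicative_stdp_factors]).
#' @return An object of class `spiking_rule`.
#' @export
spiking_rule <- function(orientation = c("reverse", "classical"),
                         alpha = 1.2, A_plus = 0.01, tau_stdp = 20,
                         W_max = 50, multiplicative = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(alpha > 0, A_plus >= 0, tau_stdp > 0, W_max > 0)
  structure(list(orientation = orientation, alpha = alpha, A_plus = A_plus,
                 tau_stdp = tau_stdp, W_max = W_max,
                 multiplicative = isTRUE(multiplicative)),
            class = "spiking_rule")
}

#' Stopping criteria for the spiking engine
#'
#' @param extreme_fraction Fraction of weights at the bounds that triggers
#'   the `"extreme_weights"` outcome.
#' @param extreme_margin Distance (weight units) from `W_max` or `-W_max`
#'   within which a weight counts as at the bound.
#' @param corr_lag Lag (presentations) for the weight stability correlation.
#' @param corr_thresh Correlation threshold for stability.
#' @param std_lag Lag (presentations) over which the relative change of the
#'   weight standard deviation is measured.
#' @param std_change_fraction Maximum relative change of the weight standard
#'   deviation over `std_lag` for stability.
#' @param std_slope_abs Alternative absolute stability criterion: the weight
#'   standard deviation is also considered stable when
#'   `|std(N) - std(N - std_lag)| / std_lag` falls below this slope (std
#'   units per presentation). Either condition suffices.
#' @param diversity_std_thresh Weight standard deviation separating
#'   `"weights_too_similar"` (below) from `"converged"` (above) once the
#'   weights have stabilized.
#' @param max_presentations Presentation cap; reaching it yields
#'   `"did_not_converge"`.
#' @return An object of class `spiking_stop_criteria`.
#' @export
spiking_stop_criteria <- function(extreme_fraction = 0.50,
                                  extreme_margin = 0.1,
                                  corr_lag = 3000L, corr_thresh = 0.99,
                                  std_lag = 6000L,
                                  std_change_fraction = 0.001,
                                  std_slope_abs = 1e-5,
                                  diversity_std_thresh = 0.3,
                                  max_presentations = 625000L) {
  stopifnot(extreme_fraction > 0, extreme_margin > 0, corr_lag > 0,
            corr_thresh > 0, std_lag > 0, std_change_fraction > 0,
            std_slope_abs > 0, diversity_std_thresh > 0, corr_lag < std_lag,
            std_lag <= max_presentations)
  structure(list(extreme_fraction = extreme_fraction,
                 extreme_margin = extreme_margin,
                 corr_lag = as.integer(corr_lag),
                 corr_thresh = corr_thresh, std_lag = as.integer(std_lag),
                 std_change_fraction = std_change_fraction,
                 std_slope_abs = std_slope_abs,
                 diversity_std_thresh = diversity_std_thresh,
                 max_presentations = as.integer(max_presentations)),
            class = "spiking_stop_criteria")
}
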