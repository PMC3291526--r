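#' Weaken and centre the bottom-up matrix for the reconstruction regime
#'
#' Transforms a generated bottom-up matrix into the weak-drive regime used
#' by the input-reconstruction experiment: `Q' = 2 Q - mean(2 Q) + 0.5`
#' (the mean is the scalar mean over all entries, so `mean(Q')` is exactly
#' 0.5). With near-zero-mean bottom-up weights, overall drive is weak and
#' only neurons with stronger inputs fire, which makes firing rates track
#' input strength.
#'
#' @param Q Bottom-up weight matrix from [generate_bottom_up_matrix].
#' @return The transformed matrix.
#' @export
reconstruction_transform_Q <- function(Q) {
  2 * Q - mean(2 * Q) + 0.5
}

#' Early-input reconstruction probe of a trained network
#'
#' Quantifies how well late lower-layer activity, driven through the
#' learned top-down connections, reconstructs the early stimulus-driven
#' activity. For each stimulus, the network is probed with an input
#' envelope that is zeroed after `early_ms`; per-neuron spike counts are
#' taken in the early window (`0 .. early_ms`) and the late window
#' (`late_start_ms .. presentation end`). The late counts of a
#' zero-top-down network probed with the same stimulus are subtracted as a
#' baseline, and the Pearson correlation between the early vector and the
#' baseline-subtracted late vector is recorded. Zero-variance vectors give
#' a correlation of 0 and are flagged.
#'
#' @param W Trained top-down weight matrix.
#' @param Q Bottom-up weight matrix (typically transformed by
#'   [reconstruction_transform_Q]).
#' @param lif A [lif_config].
#' @param ensemble A [stimulus_ensemble].
#' @param n_stimuli Number of distinct external stimuli to probe.
#' @return A list with `correlations` (length `n_stimuli`), `mean`, `sd`,
#'   and `n_flagged` (stimuli with degenerate variance).
#' @export
reconstruction_probe <- function(W, Q, lif, ensemble, n_stimuli = 100L) {
  early_ms <- 50L
  late_start_ms <- ensemble$transient_ms
  tt <- seq(0, ensemble$presentation_ms - lif$dt, by = lif$dt)
  envelope <- input_time_course(tt, ensemble)
  envelope[tt >= early_ms] <- 0
  W0 <- matrix(0, nrow(W), ncol(W))
  early_idx <- which(tt < early_ms)
  late_idx <- which(tt >= late_start_ms)
  Csqrt <- sym_sqrt(ensemble$C_input)
  n_lower <- lif$n_lower
  cors <- numeric(n_stimuli)
  flagged <- 0L
  for (s in seq_len(n_stimuli)) {
    Jbar <- pmax(ensemble$J_mean +
                   (ensemble$J_mean / 4) * as.vector(Csqrt %*% rnorm(n_lower)),
                 0)
    rec <- run_presentation_spiking(W, Q, lif, ensemble, Jbar,
                                    envelope = envelope)
    rec0 <- run_presentation_spiking(W0, Q, lif, ensemble, Jbar,
                                     envelope = envelope)
    early <- rowSums(rec$lower_spikes[, early_idx, drop = FALSE])
    late <- rowSums(rec$lower_spikes[, late_idx, drop = FALSE]) -
      rowSums(rec0$lower_spikes[, late_idx, drop = FALSE])
    if (sd(early) == 0 || sd(late) == 0) {
      cors[s] <- 0
      flagged <- flagged + 1L
    } else {
      cors[s] <- cor(early, late)
    }
  }
  list(correlations = cors, mean = mean(cors), sd = sd(cors),
       n_flagged = flagged)
}

#' Input-reconstruction experiment across training checkpoints
#'
#' Trains the spiking network with the given rule on the weak-drive
#' (transformed) bottom-up matrix, pausing at each checkpoint to run the
#' reconstruction probe over `n_stimuli` stimuli. As training progresses
#' the top-down weights increasingly recreate a scaled version of the
#' original input, so the mean correlation rises with the checkpoint index.
#'
#' @param Q Bottom-up matrix already in the weak-drive regime.
#' @param lif A [lif_config].
#' @param ensemble A [stimulus_ensemble].
#' @param rule A [spiking_rule] (depression-biased reverse in the standard
#'   experiment).
#' @param checkpoints Increasing vector of presentation counts at which to
#'   probe.
#' @param n_stimuli Stimuli per probe.
#' @return A data frame with one row per checkpoint: `checkpoint`,
#'   `mean_correlation`, `sd_correlation`, `n_flagged`; the final weights
#'   are attached as attribute `"W"`.
#' @export
reconstruction_experiment <- function(Q, lif, ensemble, rule,
                                      checkpoints = c(10, 100, 1000, 10000,
                                                      51000),
                                      n_stimuli = 100L) {
  stopifnot(all(diff(checkpoints) > 0), length(checkpoints) >= 1)
  envelope <- input_time_course(seq(0, ensemble$presentation_ms - lif$dt,
                                    by = lif$dt), ensemble)
  Csqrt <- sym_sqrt(ensemble$C_input)
  n_lower <- lif$n_lower
  W <- initial_spiking_weights(lif$n_lower, lif$n_higher)
  out <- data.frame(checkpoint = checkpoints,
                    mean_correlation = NA_real_,
                    sd_correlation = NA_real_, n_flagged = NA_integer_)
  n <- 0L
  for (k in seq_along(checkpoints)) {
    while (n < checkpoints[k]) {
      n <- n + 1L
      Jbar <- pmax(ensemble$J_mean +
                     (ensemble$J_mean / 4) *
                       as.vector(Csqrt %*% rnorm(n_lower)), 0)
      rec <- run_presentation_spiking(W, Q, lif, ensemble, Jbar,
                                      envelope = envelope)
      if (rec$pathological) {
        stop("reconstruction_experiment: pathological membrane dynamics")
      }
      sums <- cpp_stdp_pair_sums(rec$lower_spikes, rec$higher_spikes,
                                 rule$tau_stdp)
      W <- pmin(pmax(W + stdp_compose_delta(rule, sums, W), -rule$W_max),
                rule$W_max)
    }
    pr <- reconstruction_probe(W, Q, lif, ensemble, n_stimuli)
    out$mean_correlation[k] <- pr$mean
    out$sd_correlation[k] <- pr$sd
    out$n_flagged[k] <- pr$n_flagged
  }
  attr(out, "W") <- W
  out
}
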