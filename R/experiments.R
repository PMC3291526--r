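#' Specification of a parameter sweep
#'
#' Describes a full-factorial sweep over simulation parameters for one of
#' the two engines. Every combination of the grid values is run with
#' `replicates` independent seeds drawn from a [seed_registry].
#'
#' @param grid Named list mapping parameter names to value vectors.
#'   Recognized names for the spiking engine: `orientation`, `alpha`,
#'   `d_ms`, `tau_stdp_ms`, `S`, `tau_syn_ms`, `sigma_input`, `sigma_noise`,
#'   `W_max`; for the linear engine: `orientation`, `alpha`, `mu`.
#' @param engine `"spiking"` or `"linear"`.
#' @param replicates Seeds per grid cell.
#' @param n_lower,n_higher Layer sizes.
#' @param max_presentations Presentation cap per run.
#' @param base Named list of fixed parameter overrides applied to every cell.
#' @param n_ref Reference layer size of the full-scale spiking model. When
#'   `n_lower < n_ref`, each spiking run applies the desk-scaling rule:
#'   inter-layer conductance increments and the STDP amplitude are both
#'   multiplied by `n_ref / n_lower`, preserving the aggregate cross-layer
#'   drive per neuron and the number of presentations needed to traverse
#'   the weight range (see the methods vignette).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(grid, engine = c("spiking", "linear"),
                       replicates = 3L, n_lower = 30L, n_higher = 30L,
                       max_presentations = 50000L, base = list(),
                       n_ref = 100L) {
  engine <- match.arg(engine)
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)),
            replicates >= 1, n_ref >= 1)
  structure(list(grid = grid, engine = engine,
                 replicates = as.integer(replicates),
                 n_lower = as.integer(n_lower),
                 n_higher = as.integer(n_higher),
                 max_presentations = as.integer(max_presentations),
                 base = base, n_ref = as.integer(n_ref)),
            class = "sweep_spec")
}

#' Desk-scale sweep preset
#'
#' A reduced sweep that preserves the categorical contrast between the four
#' rule classes (classical/reverse crossed with depression/potentiation
#' bias) at desk scale: 30 neurons per layer with the desk-scaling rule
#' applied (see [sweep_spec]), the STDP window at the middle of its
#' full-grid range (10 ms), the example-configuration values for the
#' two-valued timing parameters (delay 15 ms, synaptic time constant
#' 15 ms), noise 1500 spikes/s with 150% input/noise variability, weight
#' bound 35, a 50,000-presentation cap and 3 seeds per cell.
#'
#' @param alphas Depression/potentiation balance values to cross with both
#'   orientations.
#' @param replicates Seeds per cell.
#' @param max_presentations Presentation cap.
#' @return A [sweep_spec].
#' @export
desk_sweep_preset <- function(alphas = c(0.9, 1.2, 3), replicates = 3L,
                              max_presentations = 50000L) {
  sweep_spec(grid = list(orientation = c("classical", "reverse"),
                         alpha = alphas),
             engine = "spiking", replicates = replicates,
             n_lower = 30L, n_higher = 30L,
             max_presentations = max_presentations,
             base = list(d_ms = 15, tau_stdp_ms = 10, S = 1500,
                         tau_syn_ms = 15, sigma_input = 1.5,
                         sigma_noise = 1.5, W_max = 35))
}

spiking_cell_params <- function(spec, cell) {
  p <- utils::modifyList(list(d_ms = 15, tau_stdp_ms = 20, S = 2000,
                              tau_syn_ms = 15, sigma_input = 1,
                              sigma_noise = 0.5, W_max = 50,
                              orientation = "reverse", alpha = 1.2,
                              A_plus = 0.01),
                         spec$base)
  utils::modifyList(p, cell)
}

run_sweep_cell_spiking <- function(spec, params, seed) {
  set.seed(seed)
  scale <- spec$n_ref / spec$n_lower
  Q <- generate_bottom_up_matrix(spec$n_lower, spec$n_higher, epsilon = 0.1)
  C <- build_input_correlation(spec$n_lower)
  lif <- lif_config(tau_syn = params$tau_syn_ms, delay = params$d_ms,
                    noise_S = params$S, sigma_noise = params$sigma_noise,
                    n_lower = spec$n_lower, n_higher = spec$n_higher,
                    coupling_gain = scale)
  ens <- stimulus_ensemble(C, sigma_input = params$sigma_input)
  rule <- spiking_rule(params$orientation, alpha = params$alpha,
                       A_plus = params$A_plus * scale,
                       tau_stdp = params$tau_stdp_ms, W_max = params$W_max)
  # desk scaling runs the weight dynamics `scale` times faster on a
  # `scale` times dilated weight axis, so the presentation-denominated
  # stability lags contract and the absolute std-slope threshold dilates
  # accordingly (see the methods vignette)
  stride <- 100L
  lag <- function(l) max(stride, as.integer(round(l / scale / stride)) * stride)
  crit <- spiking_stop_criteria(corr_lag = lag(3000L),
                                std_lag = lag(6000L),
                                std_slope_abs = 1e-5 * scale^2,
                                max_presentations = spec$max_presentations)
  res <- train_spiking(Q, lif, ens, rule, crit, stride = stride)
  list(outcome = res$outcome, std_W = sd(as.vector(res$W)))
}

run_sweep_cell_linear <- function(spec, params, seed) {
  set.seed(seed)
  Q <- generate_bottom_up_matrix(spec$n_lower, spec$n_higher,
                                 epsilon = 0.1, smooth_width = 3)
  C <- build_input_correlation(spec$n_lower)
  W0 <- initial_top_down_matrix(spec$n_lower, spec$n_higher)
  rule <- linear_rule(params$orientation, alpha = params$alpha,
                      mu = if (is.null(params$mu)) 3e-4 else params$mu)
  crit <- linear_stop_criteria(max_iterations = spec$max_presentations)
  res <- train_linear(linear_network(Q, W0), C, rule, crit)
  list(outcome = res$outcome, std_W = sd(as.vector(res$net$W)))
}

#' Run a full-factorial parameter sweep
#'
#' Executes every grid cell with `replicates` independent seeds and collects
#' one row per run. A run that raises an error is recorded with label
#' `"error"` and does not abort the sweep. With `out_dir` set, each
#' completed run is written to a JSON file named by its configuration hash
#' and already-completed runs are skipped on re-execution, so an
#' interrupted sweep resumes where it stopped.
#'
#' @param spec A [sweep_spec].
#' @param registry A [seed_registry] supplying per-run seeds.
#' @param out_dir Optional directory for resumable per-run records.
#' @param verbose Print one line per completed run.
#' @return A data frame with one row per run: the parameter values, `seed`,
#'   `label`, `n_stop`, and the final weight standard deviation `std_W`.
#' @export
run_parameter_sweep <- function(spec, registry = seed_registry(1L),
                                out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  cells <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  run_id <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- as.list(cells[ci, , drop = FALSE])
    for (rep in seq_len(spec$replicates)) {
      run_id <- run_id + 1L
      seed <- registry(run_id)
      tag <- paste0("run_", config_hash(c(cell, list(engine = spec$engine,
                                                     seed = seed))))
      cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".json"))
      row <- NULL
      if (!is.null(cache) && file.exists(cache)) {
        row <- as.data.frame(jsonlite::read_json(cache, simplifyVector = TRUE),
                             stringsAsFactors = FALSE)
      } else {
        fit <- tryCatch({
          params <- if (spec$engine == "spiking") {
            spiking_cell_params(spec, cell)
          } else cell
          if (spec$engine == "spiking") {
            run_sweep_cell_spiking(spec, params, seed)
          } else {
            run_sweep_cell_linear(spec, params, seed)
          }
        }, error = function(e) e)
        row <- cbind(as.data.frame(cell, stringsAsFactors = FALSE),
                     data.frame(seed = seed, stringsAsFactors = FALSE))
        if (inherits(fit, "error")) {
          row$label <- "error"; row$n_stop <- NA_integer_
          row$std_W <- NA_real_
        } else {
          row$label <- fit$outcome$label
          row$n_stop <- fit$outcome$n_stop
          row$std_W <- fit$std_W
        }
        if (!is.null(cache)) {
          jsonlite::write_json(row, cache, auto_unbox = TRUE, digits = 12)
        }
      }
      if (verbose) {
        message(sprintf("[%d] %s alpha=%s seed=%d -> %s (n=%s)",
                        run_id, cell$orientation, cell$alpha, seed,
                        row$label, row$n_stop))
      }
      rows[[run_id]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Rule-class label for a run
#'
#' Groups runs into the four rule classes: orientation (classical/reverse)
#' crossed with bias (depression for `alpha > 1`, potentiation otherwise).
#'
#' @param orientation `"classical"` or `"reverse"`.
#' @param alpha Depression/potentiation balance.
#' @return A character vector of class labels such as
#'   `"reverse_depression"`.
#' @export
rule_class <- function(orientation, alpha) {
  paste0(orientation, "_",
         ifelse(alpha > 1, "depression", "potentiation"))
}

#' Summarize sweep outcomes per rule class
#'
#' @param result A data frame from [run_parameter_sweep].
#' @return A data frame with one row per rule class and outcome label,
#'   giving counts and within-class proportions.
#' @export
summarize_outcomes <- function(result) {
  stopifnot(nrow(result) > 0)
  cls <- rule_class(result$orientation, result$alpha)
  tab <- table(class = cls, label = result$label)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  totals <- rowSums(tab)
  df$proportion <- df$Freq / totals[df$class]
  names(df)[names(df) == "Freq"] <- "count"
  df[order(df$class, df$label), , drop = FALSE]
}
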