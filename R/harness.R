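#' Deterministic seed registry
#'
#' Returns a closure that derives reproducible child seeds from a master
#' seed: `registry(run_id, stream)` gives an integer in `[1, 2^31 - 2]`
#' that depends only on the master seed, the run id and the stream index.
#' Derivation uses a Weyl-style mixing of the inputs with large coprime
#' multipliers modulo the Mersenne prime `2^31 - 1`, so distinct
#' (run, stream) pairs get distinct, well-separated seeds.
#'
#' @param master_seed Integer master seed.
#' @return A function `(run_id, stream = 0)` returning an integer seed.
#' @examples
#' reg <- seed_registry(1)
#' reg(1); reg(2); reg(1, stream = 1)
#' @export
seed_registry <- function(master_seed) {
  master_seed <- as.numeric(master_seed)
  stopifnot(is.finite(master_seed))
  m <- 2147483647  # 2^31 - 1
  function(run_id, stream = 0) {
    # double-precision arithmetic is exact here: all products stay < 2^53
    s <- (master_seed %% m) * 48271 %% m
    s <- (s + as.numeric(run_id) * 69621) %% m
    s <- (s * 16807 + as.numeric(stream) * 39989) %% m
    as.integer(s %% (m - 1) + 1)
  }
}

#' Short hash of a configuration
#'
#' Deterministic tag built from the sorted key/value representation of a
#' configuration list; used to name resumable sweep records.
#'
#' @param cfg Named list of scalar configuration values.
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  keys <- sort(names(cfg))
  txt <- paste(keys, vapply(cfg[keys], function(v) paste(format(v), collapse = ","),
                            ""), sep = "=", collapse = ";")
  # FNV-1a over the UTF-8 bytes, folded to 8 hex digits
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

run_config_keys <- list(
  engine = c("linear", "spiking"),
  orientation = c("classical", "reverse"),
  variant = c("none", "homeostatic", "multiplicative", "concurrent",
              "higher_input")
)

run_config_numeric <- c(
  alpha = 0, mu = 0, n_lower = 1, n_higher = 1, epsilon = 0,
  seed = -Inf, d_ms = 0, tau_stdp_ms = 0, S = -1e-12, tau_syn_ms = 0,
  sigma_input = -1e-12, sigma_noise = -1e-12, W_max = 0, A_plus = -1e-12,
  J_mean = 0, max_presentations = 0, T = 2, smooth_width = 0,
  target_rate_F = 0, eta = -1e-12, zeta = -Inf, alpha_Q = 0,
  strength_ratio = -1e-12, V_thresh = -Inf)

#' Load and validate a run configuration
#'
#' Reads a plain-text `key = value` configuration file (one pair per line;
#' `#` starts a comment). Unknown keys are rejected and every value is
#' validated against its type and allowed range before any simulation
#' starts; defaults are filled for missing keys.
#'
#' @param path Path to the configuration file.
#' @return A named list of class `run_config` with all defaults filled.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("load_config: cannot parse line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key %in% names(run_config_keys)) {
      if (!val %in% run_config_keys[[key]]) {
        stop("load_config: value '", val, "' out of range for key '", key, "'")
      }
      cfg[[key]] <- val
    } else if (key %in% names(run_config_numeric)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("load_config: non-numeric value for key '", key, "'")
      if (num <= run_config_numeric[[key]]) {
        stop("load_config: value ", val, " out of range for key '", key, "'")
      }
      cfg[[key]] <- num
    } else {
      stop("load_config: unknown key '", key, "'")
    }
  }
  defaults <- list(engine = "spiking", orientation = "reverse", alpha = 1.2,
                   mu = 3e-4, n_lower = 30, n_higher = 30, epsilon = 0.1,
                   seed = 1, d_ms = 15, tau_stdp_ms = 20, S = 2000,
                   tau_syn_ms = 15, sigma_input = 1, sigma_noise = 0.5,
                   W_max = 50, A_plus = 0.01, J_mean = 20000,
                   max_presentations = 50000, T = 9, variant = "none",
                   V_thresh = -18)
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' Writes the configuration in the same `key = value` dialect read by
#' [load_config], with keys sorted so files diff cleanly.
#'
#' @param cfg A `run_config` (or plain named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  keys <- sort(names(cfg))
  lines <- vapply(keys, function(k) {
    paste(k, format(cfg[[k]], digits = 12, scientific = FALSE), sep = " = ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Execute the run described by a configuration
#'
#' Dispatches to the linear or spiking engine with the configured rule,
#' variant and seed.
#'
#' @param cfg A `run_config` from [load_config].
#' @return The engine result list (see [train_linear], [train_spiking]).
#' @export
run_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  n_lower <- as.integer(cfg$n_lower); n_higher <- as.integer(cfg$n_higher)
  if (cfg$engine == "linear") {
    Q <- generate_bottom_up_matrix(n_lower, n_higher, epsilon = cfg$epsilon,
                                   smooth_width = cfg$smooth_width)
    C <- build_input_correlation(n_lower)
    W0 <- initial_top_down_matrix(n_lower, n_higher)
    rule <- linear_rule(cfg$orientation, alpha = cfg$alpha, mu = cfg$mu)
    crit <- linear_stop_criteria(max_iterations = cfg$max_presentations)
    train_linear(linear_network(Q, W0), C, rule, crit, T = as.integer(cfg$T))
  } else {
    Q <- generate_bottom_up_matrix(n_lower, n_higher, epsilon = cfg$epsilon)
    C <- build_input_correlation(n_lower)
    lif <- lif_config(tau_syn = cfg$tau_syn_ms, delay = cfg$d_ms,
                      noise_S = cfg$S, sigma_noise = cfg$sigma_noise,
                      V_thresh = cfg$V_thresh,
                      n_lower = n_lower, n_higher = n_higher)
    ens <- stimulus_ensemble(C, J_mean = cfg$J_mean,
                             sigma_input = cfg$sigma_input)
    rule <- spiking_rule(cfg$orientation, alpha = cfg$alpha,
                         A_plus = cfg$A_plus, tau_stdp = cfg$tau_stdp_ms,
                         W_max = cfg$W_max,
                         multiplicative = identical(cfg$variant, "multiplicative"))
    crit <- spiking_stop_criteria(max_presentations = cfg$max_presentations)
    homeo <- if (identical(cfg$variant, "homeostatic")) {
      homeostasis_params(target_rate = cfg$target_rate_F %||% 80,
                         strength = cfg$eta %||% 1)
    }
    conc <- if (identical(cfg$variant, "concurrent")) {
      concurrent_params(zeta = cfg$zeta %||% 1,
                        alpha = cfg$alpha_Q %||% cfg$alpha)
    }
    hi <- if (identical(cfg$variant, "higher_input")) {
      higher_input_params(build_input_correlation(n_higher),
                          strength_ratio = cfg$strength_ratio %||% 1)
    }
    train_spiking(Q, lif, ens, rule, crit, homeostasis = homeo,
                  concurrent = conc, higher_input = hi)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an outcome record and diagnostics to disk
#'
#' Serializes the outcome as canonical JSON (sorted keys, fixed float
#' precision, so identical runs produce byte-identical files), the
#' diagnostics trace as CSV, and the final weight matrix as CSV.
#'
#' @param result An engine result list with `outcome` and `trace` (and `W`
#'   or `net$W`).
#' @param dir Output directory, created if needed.
#' @param config Optional configuration list stored alongside (adds the
#'   config hash to the JSON record).
#' @return The paths written, invisibly.
#' @export
write_outcome <- function(result, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- list(label = result$outcome$label,
              n_stop = result$outcome$n_stop,
              diagnostics = result$outcome$diagnostics)
  if (!is.null(config)) rec$config_hash <- config_hash(config)
  rec <- rec[sort(names(rec))]
  json_path <- file.path(dir, "outcome.json")
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  trace_path <- file.path(dir, "trace.csv")
  utils::write.csv(result$trace, trace_path, row.names = FALSE)
  W <- if (!is.null(result$W)) result$W else result$net$W
  w_path <- file.path(dir, "W.csv")
  utils::write.table(W, w_path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(c(json_path, trace_path, w_path))
}

#' Read an outcome record written by [write_outcome]
#'
#' @param dir Directory containing `outcome.json`.
#' @return The outcome record as a list.
#' @export
read_outcome <- function(dir) {
  jsonlite::read_json(file.path(dir, "outcome.json"), simplifyVector = TRUE)
}
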