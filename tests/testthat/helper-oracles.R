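# Brute-force oracles used across test files.  These recompute quantities by
# direct enumeration, independently of the package's vectorized/trace-based
# implementations.

# Pairwise plasticity update of the linear engine by explicit double loop
# over adjacent time-point pairs and neuron pairs.
brute_force_linear_delta <- function(rule, trajectory) {
  L <- trajectory$L; H <- trajectory$H
  T <- trajectory$T
  n_lower <- nrow(L); n_higher <- nrow(H)
  # activity vector at an absolute time-point t (L at odd t, H at even t)
  act <- function(t) if (t %% 2 == 1) L[, (t + 1) %/% 2] else H[, t %/% 2]
  dW <- matrix(0, n_lower, n_higher)
  for (t in seq_len(T - 1)) {
    a_t <- act(t); a_t1 <- act(t + 1)
    for (i in seq_len(n_lower)) {
      for (j in seq_len(n_higher)) {
        if (t %% 2 == 1) {
          # lower at t, higher at t+1: post before pre
          joint <- a_t[i] * a_t1[j]
          dW[i, j] <- dW[i, j] + if (rule$orientation == "reverse") {
            joint
          } else -rule$alpha * joint
        } else {
          # higher at t, lower at t+1: pre before post
          joint <- a_t1[i] * a_t[j]
          dW[i, j] <- dW[i, j] + if (rule$orientation == "classical") {
            joint
          } else -rule$alpha * joint
        }
      }
    }
  }
  rule$mu * dW
}

# All-pairs exponential-window STDP sums by direct enumeration of spike
# pairs (simultaneous spikes excluded).
brute_force_pair_sums <- function(L_spk, H_spk, tau) {
  n_lower <- nrow(L_spk); n_higher <- nrow(H_spk)
  pre_post <- matrix(0, n_lower, n_higher)
  post_pre <- matrix(0, n_lower, n_higher)
  for (i in seq_len(n_lower)) {
    tL <- which(L_spk[i, ] == 1) - 1
    for (j in seq_len(n_higher)) {
      tH <- which(H_spk[j, ] == 1) - 1
      for (a in tL) {
        for (b in tH) {
          if (b < a) pre_post[i, j] <- pre_post[i, j] + exp(-(a - b) / tau)
          if (a < b) post_pre[i, j] <- post_pre[i, j] + exp(-(b - a) / tau)
        }
      }
    }
  }
  list(pre_post = pre_post, post_pre = post_pre)
}

# Random spike raster with on average `rate` spikes per neuron.
random_raster <- function(n, T, rate) {
  matrix(as.integer(runif(n * T) < rate / T), n, T)
}

# Characteristic-polynomial coefficients by Faddeev-LeVerrier, for an
# eigenvalue oracle independent of LAPACK's eigensolver.
charpoly_coefficients <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  Mk <- diag(n)
  for (k in seq_len(n)) {
    Mk <- A %*% Mk
    ck <- -sum(diag(Mk)) / k
    coefs[k + 1] <- ck
    Mk <- Mk + ck * diag(n)
  }
  coefs
}

small_lif <- function(n = 3, vth = -14, ...) {
  lif_config(n_lower = n, n_higher = n, V_thresh = vth, ...)
}
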