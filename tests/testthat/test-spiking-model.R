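test_that("temporal envelope has the transient peak, tonic plateau and zero tails", {
  ens <- stimulus_ensemble(diag(2))
  expect_equal(input_time_course(30, ens), 1)
  expect_equal(input_time_course(120, ens), 0.2)
  expect_equal(input_time_course(200, ens), 0)
  expect_equal(input_time_course(-5, ens), 0)
  tt <- input_time_course(0:159, ens)
  expect_true(all(tt >= 0 & tt <= 1))
  expect_equal(tt[81:160], rep(0.2, 80))  # tonic level is 1/5 of the peak
  expect_equal(which.max(tt), 31)         # peak at 30 ms (0-based grid)
})

test_that("membrane stays at rest without input and matches the clamped fixed point", {
  n <- 3
  lif <- small_lif(n)
  ens <- stimulus_ensemble(diag(n))
  Q <- matrix(1, n, n); W <- matrix(0, n, n)

  # zero input, zero noise, zero conductance: resting equilibrium
  quiet <- lif_config(n_lower = n, n_higher = n, V_thresh = -14,
                      noise_S = 0, sigma_noise = 0)
  ens0 <- stimulus_ensemble(diag(n), sigma_input = 0)
  rec <- run_presentation_spiking(W, Q, quiet, ens0, rep(0, n),
                                  record_V = TRUE)
  expect_equal(sum(rec$lower_spikes), 0)
  expect_equal(sum(rec$higher_spikes), 0)
  expect_true(all(abs(rec$V_lower - quiet$V_rest) < 1e-9))

  # clamped conductance, no spiking: V converges to V_rest / (1 + g)
  for (g in c(0.2, 0.5, 1.5)) {
    noth <- lif_config(n_lower = n, n_higher = n, V_thresh = 10)
    rec <- run_presentation_spiking(W, Q, noth, ens, rep(0, n),
                                    g_clamp = g, record_V = TRUE)
    expect_equal(rec$V_lower[1, ncol(rec$V_lower)],
                 lif_steady_state(g, noth), tolerance = 1e-6)
    expect_equal(lif_steady_state(g, noth), noth$V_rest / (1 + g))
  }
})

test_that("inter-spike interval under constant drive matches the closed form", {
  n <- 2
  Q <- matrix(0, n, n); W <- matrix(0, n, n)
  ens <- stimulus_ensemble(diag(n))
  for (g in c(0.45, 0.5, 0.6)) {
    lif <- lif_config(n_lower = n, n_higher = n, V_thresh = -54)
    rec <- run_presentation_spiking(W, Q, lif, ens, rep(0, n), g_clamp = g)
    spikes <- which(rec$lower_spikes[1, ] == 1)
    expect_gt(length(spikes), 3)
    isi <- diff(spikes)
    # continuous-time LIF period from reset to threshold
    v_inf <- lif$V_rest / (1 + g)
    tau_eff <- lif$tau_m / (1 + g)
    isi_pred <- tau_eff * log((v_inf - lif$V_reset) / (v_inf - lif$V_thresh))
    expect_lt(max(abs(isi - isi_pred)), 1 + 1e-9)  # within one time-step
  }
})

test_that("pairwise STDP sums equal brute-force enumeration over spike pairs", {
  set.seed(1)
  for (case in 1:6) {
    n_lower <- sample(2:5, 1); n_higher <- sample(2:5, 1)
    T <- 60
    L <- random_raster(n_lower, T, rate = sample(5:20, 1))
    H <- random_raster(n_higher, T, rate = sample(5:20, 1))
    tau <- sample(c(5, 10, 20), 1)
    got <- stdp_pair_sums(L, H, tau)
    want <- brute_force_pair_sums(L, H, tau)
    expect_equal(got$pre_post, want$pre_post, tolerance = 1e-14)
    expect_equal(got$post_pre, want$post_pre, tolerance = 1e-14)
  }
})

test_that("single spike pair gives the textbook exponential update", {
  # pre (higher) at 10 ms, post (lower) at 20 ms
  T <- 40
  L <- matrix(0L, 1, T); H <- matrix(0L, 1, T)
  L[1, 21] <- 1L  # 20 ms on the 0-based grid
  H[1, 11] <- 1L  # 10 ms
  rec <- list(lower_spikes = L, higher_spikes = H)
  W <- matrix(0, 1, 1)
  cl <- spiking_rule("classical", alpha = 1.2, A_plus = 0.01, tau_stdp = 20)
  expect_equal(stdp_weight_update(cl, rec, W)[1, 1], 0.01 * exp(-10 / 20),
               tolerance = 1e-12)
  rv <- spiking_rule("reverse", alpha = 1.2, A_plus = 0.01, tau_stdp = 20)
  expect_equal(stdp_weight_update(rv, rec, W)[1, 1],
               -1.2 * 0.01 * exp(-10 / 20), tolerance = 1e-12)
})

test_that("no spikes leave weights unchanged and updates clip at the bound", {
  T <- 30
  none <- list(lower_spikes = matrix(0L, 2, T),
               higher_spikes = matrix(0L, 2, T))
  W <- matrix(c(1, -2, 3, -4), 2, 2)
  rule <- spiking_rule("reverse", alpha = 3)
  expect_equal(stdp_weight_update(rule, none, W), W)

  # a large positive accumulated change clips to exactly W_max
  L <- matrix(0L, 1, T); H <- matrix(0L, 1, T)
  L[1, 19] <- 1L; H[1, 20] <- 1L  # post before pre: potentiates under rSTDP
  rec <- list(lower_spikes = L, higher_spikes = H)
  big <- spiking_rule("reverse", alpha = 1, A_plus = 10, tau_stdp = 20,
                      W_max = 50)
  expect_identical(stdp_weight_update(big, rec, matrix(49.999, 1, 1))[1, 1],
                   50)
})

test_that("simultaneous spikes have no defined order and are excluded", {
  T <- 20
  L <- matrix(0L, 1, T); H <- matrix(0L, 1, T)
  L[1, 10] <- 1L; H[1, 10] <- 1L
  s <- stdp_pair_sums(L, H, 20)
  expect_equal(s$pre_post[1, 1], 0)
  expect_equal(s$post_pre[1, 1], 0)
})

test_that("every emitted spike lands in exactly one neuron and time bin", {
  set.seed(2)
  n <- 5
  lif <- small_lif(n, vth = -30)
  C <- build_input_correlation(n)
  ens <- stimulus_ensemble(C)
  Q <- generate_bottom_up_matrix(n, n, epsilon = 0.1)
  W <- initial_spiking_weights(n, n)
  rec <- run_presentation_spiking(W, Q, lif, ens,
                                  sample_input_strengths(C, 20000))
  expect_true(all(rec$lower_spikes %in% c(0L, 1L)))
  expect_true(all(rec$higher_spikes %in% c(0L, 1L)))
  expect_equal(dim(rec$lower_spikes), c(n, 160))
  dur <- ens$presentation_ms / 1000
  expect_equal(rec$rate_lower, sum(rec$lower_spikes) / n / dur)
  expect_equal(rec$rate_higher, sum(rec$higher_spikes) / n / dur)
})
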