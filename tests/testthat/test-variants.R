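test_that("homeostatic factor is 1 at the set-point and restores towards it", {
  p <- homeostasis_params(target_rate = 80, strength = 100)
  W <- matrix(1, 3, 4); gain <- rep(1, 3)

  at_target <- homeostatic_rescale(W, gain, rep(80, 3), p)
  expect_equal(at_target$W, W)
  expect_equal(at_target$input_gain, gain)
  expect_equal(at_target$factors, rep(1, 3))

  # above target shrinks the total input gain, below target grows it
  hi <- homeostatic_rescale(W, gain, rep(160, 3), p)
  expect_true(all(hi$factors < 1))
  expect_true(all(hi$input_gain < gain))
  expect_true(all(hi$W < W))
  lo <- homeostatic_rescale(W, gain, rep(40, 3), p)
  expect_true(all(lo$factors > 1))

  # monotone in the rate error: sign of the factor offset follows F - r
  rates <- c(20, 79, 80, 81, 200)
  f <- homeostatic_rescale(matrix(1, 5, 2), rep(1, 5), rates, p)$factors
  expect_equal(sign(f - 1), sign(80 - rates))

  # clip guards the zero-rate and huge-strength cases
  z <- homeostatic_rescale(matrix(1, 1, 1), 1, 0, p)
  expect_equal(z$factors, p$clip[2])
})

test_that("homeostasis is applied only on interval boundaries during training", {
  set.seed(1)
  n <- 4
  Q <- generate_bottom_up_matrix(n, n, epsilon = 0.1)
  C <- build_input_correlation(n)
  W0 <- initial_top_down_matrix(n, n)
  homeo <- homeostasis_params(target_rate = 1, strength = 100, interval = 30L)
  # frozen plasticity isolates the homeostatic rescaling: with mu ~ 0 the
  # only weight changes can come from the interval rescale
  rule <- linear_rule("reverse", alpha = 3, mu = 1e-300)
  res <- train_linear(linear_network(Q, W0), C, rule,
                      linear_stop_criteria(max_iterations = 65),
                      homeostasis = homeo)
  tr <- res$trace
  changed <- which(abs(diff(tr$std_W)) > 1e-12) + 1L
  expect_true(all(changed %% 30L %in% c(0L, 1L)))
  expect_gt(length(changed), 0)
})

test_that("multiplicative soft-bound factors vanish at the ceiling and the floor", {
  f <- multiplicative_stdp_factors(c(-20, 0, 10, 50), 50)
  expect_equal(f$pot_factor, c(70, 50, 40, 0) / 50)
  expect_equal(f$dep_factor, c(20, 0, 10, 50) / 50)
})

test_that("the multiplicative update map drives weights to strong-or-weak fixed points", {
  # single-unit toy (Q = q, C = 1, T = 3): the soft-bound rule is quadratic
  # in w, so its attracting fixed points sit near zero or near W_max.
  # Closed forms solved by hand from the pair sums (post-before-pre = q,
  # pre-before-post = q^2 w):
  #   reverse:   q (Wmax - w) - alpha q^2 w^2 = 0
  #   classical: q^2 w (Wmax - w) - alpha q w = 0  ->  w = Wmax - alpha/q
  q <- 5; Wmax <- 50; alpha <- 1.2
  iterate <- function(w0, orient) {
    rule <- linear_rule(orient, alpha = alpha, mu = 1e-3,
                        multiplicative = TRUE, W_max = Wmax)
    w <- w0
    for (k in 1:30000) {
      net <- linear_network(matrix(q, 1, 1), matrix(w, 1, 1))
      w <- w + expected_stdp_delta(net, matrix(1, 1, 1), rule, T = 3)[1, 1]
    }
    w
  }
  fp_rev <- (-q + sqrt(q^2 + 4 * alpha * q^3 * Wmax)) / (2 * alpha * q^2)
  fp_cls <- Wmax - alpha / q
  for (w0 in c(1, 10, 30, 49)) {
    wr <- iterate(w0, "reverse")
    expect_equal(wr, fp_rev, tolerance = 1e-6)
    expect_lt(abs(wr), 0.2 * Wmax)           # weak attractor near zero
    wc <- iterate(w0, "classical")
    expect_equal(wc, fp_cls, tolerance = 1e-6)
    expect_gt(wc, 0.8 * Wmax)                # strong attractor near the bound
  }
})

test_that("concurrent bottom-up update follows the single-pair formula and clips", {
  T <- 40
  L <- matrix(0L, 1, T); H <- matrix(0L, 1, T)
  L[1, 11] <- 1L  # lower at 10 ms
  H[1, 21] <- 1L  # higher at 20 ms: pre-before-post from Q's viewpoint
  rec <- list(lower_spikes = L, higher_spikes = H)
  rule <- spiking_rule("reverse", alpha = 1.2, A_plus = 0.01, tau_stdp = 20)
  params <- concurrent_params(zeta = 2, alpha = 1.5, orientation = "classical")
  Q0 <- matrix(0, 1, 1)
  Q1 <- concurrent_bottom_up_update(Q0, params, rule, rec)
  expect_equal(Q1[1, 1], 2 * 0.01 * exp(-10 / 20), tolerance = 1e-12)

  # zero activity leaves Q unchanged
  none <- list(lower_spikes = matrix(0L, 1, T),
               higher_spikes = matrix(0L, 1, T))
  expect_equal(concurrent_bottom_up_update(Q0, params, rule, none), Q0)

  # sign of zeta selects the orientation when not given explicitly
  expect_equal(concurrent_params(zeta = -1)$orientation, "reverse")
  expect_equal(concurrent_params(zeta = 1)$orientation, "classical")
})

test_that("higher-layer drive scales with the strength ratio and vanishes at zero", {
  set.seed(2)
  C <- build_input_correlation(6)
  ens <- stimulus_ensemble(C)
  expect_null(higher_layer_drive(higher_input_params(C, 0), ens))
  for (ratio in c(0.1, 1, 10)) {
    draws <- replicate(3000, mean(higher_layer_drive(
      higher_input_params(C, ratio), ens)))
    expect_equal(mean(draws), ratio * ens$J_mean,
                 tolerance = 0.03)
    expect_true(all(draws >= 0))
  }
})

test_that("homeostatic scaling closes the loop: lower-layer rates approach the target", {
  set.seed(21)
  n <- 30; sc <- 100 / n
  Q <- generate_bottom_up_matrix(n, n, epsilon = 0.1)
  lif <- lif_config(n_lower = n, n_higher = n, coupling_gain = sc)
  ens <- stimulus_ensemble(build_input_correlation(n))
  crit <- spiking_stop_criteria(corr_lag = 900L, std_lag = 1800L,
                                max_presentations = 4000L)
  rule <- spiking_rule("reverse", alpha = 1.2, A_plus = 0.01 * sc)
  res <- train_spiking(Q, lif, ens, rule, crit,
                       homeostasis = homeostasis_params(target_rate = 80,
                                                        strength = 100))
  late <- mean(tail(res$trace$rate_lower, 10))
  expect_lt(abs(late - 80) / 80, 0.2)
  # scaling engaged: the external-input gains moved off their initial value
  expect_true(any(abs(res$input_gain - 1) > 0.05))
})

test_that("homeostatic scaling preserves convergence of depression-biased reverse learning", {
  set.seed(2)
  Q <- generate_bottom_up_matrix(10, 10, epsilon = 0.1)
  C <- build_input_correlation(10)
  W0 <- initial_top_down_matrix(10, 10)
  res <- train_linear(linear_network(Q, W0), C, linear_rule("reverse", alpha = 3),
                      linear_stop_criteria(max_iterations = 30000),
                      homeostasis = homeostasis_params(target_rate = 1,
                                                       strength = 10))
  expect_equal(res$outcome$label, "converged")
  expect_true(all(res$trace$max_eig <= 1))
})

test_that("concurrent bottom-up plasticity keeps the orientation requirement for W", {
  runc <- function(seed, orient) {
    set.seed(seed)
    n <- 30; sc <- 100 / n
    Q <- generate_bottom_up_matrix(n, n, epsilon = 0.1)
    lif <- lif_config(n_lower = n, n_higher = n, coupling_gain = sc)
    ens <- stimulus_ensemble(build_input_correlation(n))
    crit <- spiking_stop_criteria(corr_lag = 900L, std_lag = 1800L,
                                  std_slope_abs = 1e-5 * sc^2,
                                  max_presentations = 40000L)
    rule <- spiking_rule(orient, alpha = 1.2, A_plus = 0.01 * sc)
    train_spiking(Q, lif, ens, rule, crit,
                  concurrent = concurrent_params(zeta = 1, alpha = 1.2))
  }
  res_rev <- runc(1, "reverse")
  expect_equal(res_rev$outcome$label, "converged")
  expect_gt(sd(res_rev$W), 0.3)
  # bottom-up weights actually moved and stayed within the bound
  expect_lte(max(abs(res_rev$Q)), 50)
  res_cls <- runc(4, "classical")
  expect_equal(res_cls$outcome$label, "extreme_weights")
})
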