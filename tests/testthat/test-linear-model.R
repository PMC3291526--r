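test_that("activity propagation follows the alternating two-layer dynamics", {
  set.seed(1)
  Q <- generate_bottom_up_matrix(4, 4, epsilon = 0.1)
  x <- rnorm(4)

  # zero feedback: lower activity vanishes after the input time-point
  net0 <- linear_network(Q, matrix(0, 4, 4))
  tr <- simulate_presentation_linear(net0, x, T = 9)
  expect_equal(tr$L[, 1], x)
  expect_equal(tr$H[, 1], as.vector(Q %*% x))
  expect_true(all(tr$L[, -1] == 0))

  # identity loop with gain 0.5: closed-form geometric decay (W Q)^k x
  net <- linear_network(diag(4), 0.5 * diag(4))
  tr <- simulate_presentation_linear(net, x, T = 11)
  for (k in 0:(ncol(tr$L) - 1)) {
    expect_equal(tr$L[, k + 1], 0.5^k * x, tolerance = 1e-12)
  }

  # scaled-inverse feedback: each round trip shrinks activity by 1/3,
  # matching a maximum loop eigenvalue of 1/3
  W <- solve(Q) / 3
  net3 <- linear_network(Q, W)
  tr <- simulate_presentation_linear(net3, x, T = 9)
  norms <- sqrt(colSums(tr$L^2))
  expect_equal(norms[-1] / norms[-length(norms)],
               rep(1 / 3, length(norms) - 1), tolerance = 1e-10)
  expect_equal(max_loop_gain(Q, W), 1 / 3, tolerance = 1e-12)
})

test_that("pairwise update matches a brute-force loop over time and neuron pairs", {
  set.seed(2)
  for (case in 1:8) {
    n_lower <- sample(1:4, 1); n_higher <- sample(1:4, 1)
    T <- sample(c(3, 5, 7), 1)
    net <- linear_network(matrix(rnorm(n_higher * n_lower), n_higher, n_lower),
                          matrix(rnorm(n_lower * n_higher, sd = 0.3),
                                 n_lower, n_higher))
    x <- rnorm(n_lower)
    traj <- simulate_presentation_linear(net, x, T)
    for (orient in c("classical", "reverse")) {
      rule <- linear_rule(orient, alpha = runif(1, 0.5, 3), mu = 0.1)
      expect_equal(stdp_delta_linear(rule, traj),
                   brute_force_linear_delta(rule, traj),
                   tolerance = 1e-14)
    }
  }
})

test_that("single-synapse update enumerates the two adjacent-pair terms", {
  # L(1)=2, H(2)=3, L(3)=1: post-before-pre term 2*3, pre-before-post 3*1
  traj <- structure(list(L = matrix(c(2, 1), 1), H = matrix(3, 1),
                         T = 3L, finite = TRUE),
                    class = "activity_trajectory")
  cl <- linear_rule("classical", alpha = 2, mu = 0.1)
  expect_equal(stdp_delta_linear(cl, traj),
               matrix(0.1 * (3 * 1 - 2 * (2 * 3)), 1, 1))
  rv <- linear_rule("reverse", alpha = 2, mu = 0.1)
  expect_equal(stdp_delta_linear(rv, traj),
               matrix(0.1 * (2 * 3 - 2 * (3 * 1)), 1, 1))
})

test_that("update vanishes for zero activity and for the balanced case", {
  net <- linear_network(diag(3), matrix(0, 3, 3))
  traj <- simulate_presentation_linear(net, rep(0, 3), T = 7)
  rule <- linear_rule("classical", alpha = 2, mu = 1)
  expect_equal(stdp_delta_linear(rule, traj), matrix(0, 3, 3))

  # alpha = 1 with identity loop gain 1: every post-before-pre product
  # equals its matching pre-before-post product, so the rule is antisymmetric
  net1 <- linear_network(diag(3), diag(3))
  traj1 <- simulate_presentation_linear(net1, c(1, -2, 0.5), T = 9)
  bal <- linear_rule("reverse", alpha = 1, mu = 1)
  expect_equal(stdp_delta_linear(bal, traj1), matrix(0, 3, 3),
               tolerance = 1e-12)
})

test_that("expected update equals the per-stimulus update averaged over the ensemble", {
  set.seed(3)
  n <- 4
  Q <- generate_bottom_up_matrix(n, n, epsilon = 0.1)
  W <- matrix(rnorm(n * n, sd = 0.02), n, n)
  net <- linear_network(Q, W)
  rule <- linear_rule("reverse", alpha = 2, mu = 1)
  # a rank-one ensemble concentrated on a single stimulus x has C = x x^T,
  # for which the expected update must equal the single-trajectory update
  x <- rnorm(n)
  C1 <- x %*% t(x)
  traj <- simulate_presentation_linear(net, x, T = 9)
  expect_equal(expected_stdp_delta(net, C1, rule, T = 9),
               stdp_delta_linear(rule, traj), tolerance = 1e-10)
})

test_that("predicted fixed point nulls the expected update", {
  set.seed(4)
  Q <- generate_bottom_up_matrix(6, 6, epsilon = 0.1)
  C <- build_input_correlation(6)
  for (orient in c("reverse", "classical")) {
    for (alpha in c(1.2, 2, 3)) {
      rule <- linear_rule(orient, alpha = alpha, mu = 1)
      Wstar <- predicted_fixed_point(Q, rule)
      lg <- loop_gain_spectrum(Q, Wstar)
      target <- if (orient == "reverse") 1 / alpha else alpha
      expect_equal(Mod(lg$values), rep(target, 6), tolerance = 1e-8)
      dW <- expected_stdp_delta(linear_network(Q, Wstar), C, rule, T = 9)
      expect_lt(max(abs(dW)) / max(abs(Wstar)), 1e-8)
    }
  }
  expect_equal(predicted_fixed_point(diag(3), linear_rule("reverse", alpha = 2)),
               0.5 * diag(3))
  expect_error(predicted_fixed_point(matrix(1, 3, 3),
                                     linear_rule("reverse", alpha = 2)),
               "condition number")
})

test_that("loop-gain spectrum matches an independent characteristic-polynomial solver", {
  set.seed(5)
  Q <- matrix(rnorm(25), 5, 5)
  W <- matrix(rnorm(25, sd = 0.4), 5, 5)
  lg <- loop_gain_spectrum(Q, W)
  roots <- polyroot(rev(charpoly_coefficients(W %*% Q)))
  expect_equal(sort(Mod(lg$values)), sort(Mod(roots)), tolerance = 1e-8)

  expect_equal(loop_gain_spectrum(Q, matrix(0, 5, 5))$max_modulus, 0)
  expect_false(loop_gain_spectrum(Q, matrix(0, 5, 5))$strong_loop)
  W2 <- 2 * solve(Q)
  lg2 <- loop_gain_spectrum(Q, W2)
  expect_equal(Mod(lg2$values), rep(2, 5), tolerance = 1e-8)
  expect_true(lg2$strong_loop)
})

test_that("bottom-up expected update vanishes at the role-swapped fixed point", {
  set.seed(6)
  W <- generate_bottom_up_matrix(5, 5, epsilon = 0.1) / 5
  C <- build_input_correlation(5)
  rule <- linear_rule("classical", alpha = 2.5, mu = 1)
  Qstar <- solve(W) / 2.5
  dQ <- expected_stdp_delta_bottom_up(linear_network(Qstar, W), C, rule, T = 9)
  expect_lt(max(abs(dQ)) / max(abs(Qstar)), 1e-8)
})
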