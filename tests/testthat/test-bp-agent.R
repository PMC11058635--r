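test_that("steady-state gain has the right limits and fixed-point value", {
  expect_equal(steady_state_gain(0, 1), 0)
  expect_equal(steady_state_gain(1, 0), 1)
  expect_equal(steady_state_gain(1, 1), 0.6180, tolerance = 1e-4)
  expect_error(steady_state_gain(0, 0), class = "contpsych_config_error")

  # strictly increasing in the variance ratio
  r <- c(0.001, 0.01, 0.1, 1, 10, 100)
  k <- vapply(r, function(ri) steady_state_gain(ri, 1), numeric(1))
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= 0 & k <= 1))
})

test_that("closed-form gain matches the iterated Kalman variance recursion", {
  for (r in c(0.01, 0.1, 1, 10, 100)) {
    expect_equal(steady_state_gain(r, 1), iterated_gain(r, 1),
                 tolerance = 1e-6)
  }
})

test_that("constant-gain filter matches a grid-based sequential Bayes oracle", {
  set.seed(21)
  for (r in c(0.1, 1, 10)) {
    process_var <- r
    obs_var <- 1
    x <- cumsum(stats::rnorm(50, 0, sqrt(process_var)))
    obs <- x + stats::rnorm(50, 0, sqrt(obs_var))
    oracle <- grid_posterior_means(obs, process_var, obs_var)
    k <- steady_state_gain(process_var, obs_var)
    est <- constant_gain_filter(obs, k)
    # after the gain recursion has converged the two agree closely
    expect_lt(max(abs(est[26:50] - oracle[26:50])), 1e-3)
  }
})

test_that("degenerate filter gains pass observations or predictions through", {
  obs <- c(1, 2, 3, 4)
  expect_equal(constant_gain_filter(obs, 1), obs)
  expect_equal(constant_gain_filter(obs, 0), rep(1, 4))
  expect_error(constant_gain_filter(obs, 1.5),
               class = "contpsych_config_error")
})

test_that("perception follows the horizontal-component rule", {
  expect_equal(as.numeric(perceive(x_hat = 50, y_hat = 20, beta = 0)), 20)
  expect_equal(as.numeric(perceive(x_hat = 0, y_hat = 20, beta = 0.7)), 20)
  # hand-evaluated: sin(20 deg) - 0.7 sin(30 deg) = -0.00798
  expect_equal(as.numeric(perceive(x_hat = 30, y_hat = 20, beta = 0.7)),
               -0.457, tolerance = 1e-3)
  # clipping is counted
  out <- perceive(x_hat = -90, y_hat = 80, beta = 0.9)
  expect_equal(attr(out, "clipped"), 1L)
  expect_equal(as.numeric(out), 90)
})

test_that("the damped spring acts only on nonzero error and can overshoot", {
  expect_equal(act_step(0, 0, b = 0.375, c = 0.4, dt = DT)$a, 0)

  # weakly damped spring overshoots a 10 degree step
  r <- spring_step_response(0.375, 0.008, 0, dt = DT, duration = 20,
                            step = 10)
  expect_gt(max(r), 10)

  # any stable spring nulls a constant error in the long run
  r2 <- spring_step_response(0.375, 0.8, 0, dt = DT, duration = 120,
                             step = 10)
  expect_lt(abs(r2[length(r2)] - 10), 1e-3)
})

test_that("velocity decays monotonically when the error is zero", {
  v <- 5
  for (i in 1:100) {
    v_new <- act_step(v, 0, b = 0.375, c = 0.4, dt = DT)$v
    expect_lte(abs(v_new), abs(v))
    v <- v_new
  }
})

test_that("an unstable configuration raises a stability error", {
  blob <- gen_blob_walk(step_deg = 10, duration = 300, seed = 1)
  params <- bp_params(sigma_phi2 = 0, sigma_psi2 = 0, sigma_lambda2 = 0,
                      b = 8, c = 0, delta_t = 1)
  expect_error(simulate_session(blob, params, seed = 1, mode = "training"),
               class = "contpsych_fit_error")
})

test_that("a noiseless agent with no coupling is a fixed point at goal", {
  walk <- gen_session_walk(walk_config(seed = 31))
  params <- bp_params(sigma_omega2 = 0, sigma_psi2 = 0, sigma_lambda2 = 0,
                      beta = 0)
  s <- simulate_session(walk, params, seed = 1)
  expect_equal(max(abs(s$y$values)), 0)
  # with k = 1 the estimates equal the true world states
  expect_equal(s$truth$x_hat, walk$values, tolerance = 1e-12)
})

test_that("seeded simulation is bit-reproducible", {
  walk <- gen_session_walk(walk_config(seed = 32))
  a <- simulate_session(walk, bp_params(), seed = 5)
  b <- simulate_session(walk, bp_params(), seed = 5)
  expect_identical(a$y$values, b$y$values)
  expect_identical(a$truth, b$truth)
})

test_that("the raw sin-sin regression recovers the coupling up to tracking attenuation", {
  s <- quick_session(beta = 0.71, walk_seed = 11, agent_seed = 12)
  idx <- post_idx(s)
  slope <- stats::coef(stats::lm(sin(s$y$values[idx] * pi / 180) ~
                                   sin(s$x$values[idx] * pi / 180)))[[2]]
  # the closed loop attenuates the raw slope; it stays within 0.1 of the
  # generative value under the default session conditions
  expect_lt(abs(slope - 0.71), 0.1)
})

test_that("sensation-stage adaptation pushes the dependent variable clockwise", {
  walk <- gen_session_walk(walk_config(seed = 33))
  s0 <- simulate_session(walk, bp_params(q = 0), seed = 8)
  s1 <- simulate_session(walk, bp_params(q = 1e-4), seed = 8)
  idx <- post_idx(s0)
  expect_gt(mean(s1$y$values[idx]), mean(s0$y$values[idx]))
})
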