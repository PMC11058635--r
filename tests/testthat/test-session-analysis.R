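test_that("a noiseless independent channel passes straight through", {
  s <- quick_session(params = bp_params(sigma_omega2 = 0),
                     walk_seed = 41, agent_seed = 42)
  est <- estimate_states(s, s$params)
  expect_equal(est$k_x, 1)
  expect_equal(est$x_hat$values, s$x$values)
})

test_that("a constant observation series is a filter fixed point", {
  expect_equal(constant_gain_filter(rep(5, 100), 0.3), rep(5, 100))
})

test_that("replaying the agent's sensory draws reproduces its estimate exactly", {
  s <- quick_session(walk_seed = 43, agent_seed = 44)
  est <- estimate_states(s, s$params)
  replay <- constant_gain_filter(s$truth$X, est$k_x)
  expect_lt(max(abs(replay - s$truth$x_hat)), 1e-9)
})

test_that("missing variances are a configuration error", {
  s <- quick_session(walk_seed = 43, agent_seed = 44)
  p <- s$params
  p$sigma_psi2 <- 0
  p$sigma_lambda2 <- 0
  expect_error(estimate_states(s, p), NA)  # degenerates to gain 1, allowed
  expect_error(steady_state_gain(0, 0), class = "contpsych_config_error")
})

test_that("a constant dependent estimate inverts to zero perceived deviation", {
  y_hat <- angle_series(rep(12, 500), DT)
  yt <- invert_action(y_hat, true_spring())
  expect_equal(max(abs(yt$values)), 0)
  expect_error(invert_action(y_hat, list(b = -1, c = 0.4, delta_t_hat = 0)),
               class = "contpsych_fit_error")
})

test_that("forward action then exact inversion recovers the driving error", {
  # drive the spring open loop with a known smooth error signal
  set.seed(3)
  n <- 2000L
  tt <- (1:n) * DT
  y_tilde <- 8 * sin(2 * pi * 0.05 * tt) + 4 * sin(2 * pi * 0.11 * tt + 1)
  v <- 0; y <- numeric(n); y_prev <- 0
  for (t in seq_len(n)) {
    st <- act_step(v, y_tilde[t], b = 0.375, c = 0.4, dt = DT)
    v <- st$v
    y[t] <- y_prev + st$a
    y_prev <- y[t]
  }
  fit <- list(b = 0.375, c = 0.4, delta_t_hat = 0)
  rec <- invert_action(angle_series(y, DT), fit, cutoff_hz = Inf)
  expect_gt(stats::cor(rec$values[5:n], y_tilde[5:n]), 0.9999)
})

test_that("a noiseless simulated session inverts with correlation above 0.99", {
  walk <- gen_session_walk(walk_config(seed = 45))
  p <- bp_params(sigma_omega2 = 0, sigma_psi2 = 0, sigma_lambda2 = 0)
  s <- simulate_session(walk, p, seed = 46)
  idx <- post_idx(s)
  est <- estimate_states(s, p)
  rec <- invert_action(est$y_hat, true_spring(), cutoff_hz = Inf)
  expect_gt(stats::cor(rec$values[idx], s$truth$y_tilde[idx]), 0.99)
})

test_that("a noisy simulated session inverts with correlation above 0.9", {
  s <- quick_session(walk_seed = 47, agent_seed = 48)
  idx <- post_idx(s)
  fin <- finalize(s, s$params, true_spring())
  expect_gt(stats::cor(fin$y_tilde_hat$values, s$truth$y_tilde[idx]), 0.9)
})

test_that("a noiseless uncoupled agent finalizes to the goal exactly", {
  walk <- gen_session_walk(walk_config(seed = 49))
  p <- bp_params(sigma_omega2 = 0, sigma_psi2 = 0, sigma_lambda2 = 0,
                 beta = 0)
  s <- simulate_session(walk, p, seed = 50)
  fin <- finalize(s, p, true_spring())
  expect_equal(max(abs(fin$y_star$values)), 0)
})

test_that("finalized series reduce the per-bin scatter of the dependent data", {
  s <- quick_session(walk_seed = 51, agent_seed = 52)
  idx <- post_idx(s)
  fin <- finalize(s, s$params, true_spring())
  raw_bins <- bin_series(s$x$values[idx], s$y$values[idx], lo = 0, hi = 90)
  fin_bins <- bin_series(fin$x_star, fin$y_star, lo = 0, hi = 90)
  expect_lt(mean(fin_bins$sd, na.rm = TRUE), mean(raw_bins$sd, na.rm = TRUE))
})

test_that("a correctly configured analysis leaves no residual lag", {
  s <- quick_session(walk_seed = 53, agent_seed = 54)
  fin <- finalize(s, s$params, true_spring())
  expect_lte(abs(fin$lag_residual), DT)
  # decomposed lags are reported on sensible scales
  expect_equal(fin$lag_sense, DT * (1 - fin$k_x) / fin$k_x)
  expect_gt(fin$lag_action, 0.4)
})

test_that("coupling strength is recovered from finalized series at ~2400 samples", {
  s <- quick_session(beta = 0.71, walk_seed = 55, agent_seed = 56)
  idx <- post_idx(s)
  fin <- finalize(s, s$params, true_spring())
  ff <- fit_model(fin$x_star, fin$y_star, lo = 0, hi = 90)
  fr <- fit_model(s$x$values[idx], s$y$values[idx], lo = 0, hi = 90)
  expect_equal(ff$n, 2400L)
  expect_lt(abs(ff$beta - 0.71), 0.05)
  expect_lt(abs(ff$beta - 0.71), abs(fr$beta - 0.71))
})
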