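test_that("step extraction aligns, rectifies and averages correctly", {
  ss <- synthetic_step_session(0.375, 0.4, 0.4, seed = 7)
  ex <- extract_step_responses(ss$blob, ss$target)
  # 130 s session, 10 s discard, 5 s epochs -> 24 analysed steps
  expect_equal(ex$n_steps, 24L)
  expect_equal(ex$step_size, 10)
  # noiseless rest-per-epoch responses are identical across steps
  expect_lt(max(apply(ex$segments, 1, stats::sd)), 1e-9)
  expect_equal(ex$avg, ex$segments[, 1], tolerance = 1e-12)
  # rectified: every driving step positive-going
  expect_true(all(ex$avg[50:100] > 0))
})

test_that("rectification is idempotent on an all-positive-step session", {
  m <- 100L; n_ep <- 26L
  resp <- spring_step_response(0.375, 0.4, 0.4, dt = DT, duration = 5,
                               step = 10)
  blob <- angle_series(rep(seq_len(n_ep) * 10, each = m), DT, t0 = DT)
  bases <- cumsum(c(0, rep(resp[m], n_ep - 1)))
  target <- angle_series(as.vector(vapply(seq_len(n_ep), function(k)
    bases[k] + resp, numeric(m))), DT, t0 = DT)
  ex <- extract_step_responses(blob, target)
  expect_equal(ex$avg, resp, tolerance = 1e-12)
})

test_that("fewer than two usable steps is an error", {
  blob <- angle_series(rep(c(0, 10), each = 100), DT)
  target <- angle_series(rep(0, 200), DT)
  expect_error(extract_step_responses(blob, target, discard = 0),
               class = "contpsych_data_error")
})

test_that("spring fitting recovers noiseless parameters to 1e-3 relative", {
  for (pc in list(c(0.375, 0.008), c(0.272, 0.024))) {
    ss <- synthetic_step_session(pc[1], pc[2], 0.4, seed = 7)
    ex <- extract_step_responses(ss$blob, ss$target)
    fit <- fit_spring(ex$avg, ex$step_size, DT)
    expect_lt(abs(fit$b - pc[1]) / pc[1], 1e-3)
    expect_lt(abs(fit$c - pc[2]) / pc[2], 1e-3)
    expect_lt(abs(fit$delta_t_hat - 0.4), 1e-3)
  }
})

test_that("the threshold lag estimate tracks the configured reaction lag", {
  ss <- synthetic_step_session(0.375, 0.4, 0.4, seed = 7)
  ex <- extract_step_responses(ss$blob, ss$target)
  fit <- fit_spring(ex$avg, ex$step_size, DT)
  # 5%-of-step departure happens shortly after the true 0.4 s lag
  expect_gte(fit$delta_t_threshold, 0.4)
  expect_lt(fit$delta_t_threshold, 1.5)
})

test_that("a flat response cannot be fitted", {
  expect_error(fit_spring(rep(0, 100), step_size = 0, dt = DT),
               class = "contpsych_fit_error")
  expect_error(fit_spring(rep(0, 5), step_size = 10, dt = DT),
               class = "contpsych_data_error")
})

test_that("noisy training sessions recover the spring constant within 20%", {
  tr <- simulate_training(bp_params(), seed = 13)
  fit <- fit_training(tr)
  expect_lt(abs(fit$b - 0.375) / 0.375, 0.2)
  expect_equal(fit$n_steps, 24L)
})

test_that("spring recovery holds across a seeded grid of parameter sets", {
  grid <- list(c(0.375, 0.4, 0.4), c(0.272, 0.3, 0.2), c(0.5, 0.6, 0.5),
               c(0.2, 0.25, 0.6), c(0.8, 0.9, 0.3))
  for (g in grid) {
    ss <- synthetic_step_session(g[1], g[2], g[3], seed = 17)
    ex <- extract_step_responses(ss$blob, ss$target)
    fit <- fit_spring(ex$avg, ex$step_size, DT)
    expect_lt(abs(fit$b - g[1]) / g[1], 1e-3)
    expect_lt(abs(fit$c - g[2]) / g[2], 1e-2)
    expect_lt(abs(fit$delta_t_hat - g[3]), 5e-3)
  }
})

test_that("endpoint variance uses the n-1 sample convention", {
  # two post-discard epochs with endpoint mismatches +1 and -1
  m <- 100L
  blob <- angle_series(rep(c(0, 10, 20, 10), each = m), DT, t0 = DT)
  target_vals <- rep(c(0, 10, 20, 10), each = m)
  target_vals[3 * m] <- 20 + 1   # end of third epoch
  target_vals[4 * m] <- 10 - 1   # end of fourth epoch
  target <- angle_series(target_vals, DT, t0 = DT)
  expect_equal(estimate_endpoint_variance(blob, target), 2)

  # a converged noiseless agent has zero endpoint variance
  expect_equal(estimate_endpoint_variance(blob,
                                          angle_series(rep(c(0, 10, 20, 10),
                                                           each = m), DT,
                                                       t0 = DT)), 0)
  expect_error(estimate_endpoint_variance(
    angle_series(rep(0, 50), DT), angle_series(rep(0, 50), DT)),
    class = "contpsych_data_error")
})

test_that("simulated endpoint spread matches a repeat-simulation oracle", {
  # Monte-Carlo ground truth for the endpoint variance under the default
  # noisy agent, against a single session's estimate
  set.seed(77)
  ends <- replicate(12, {
    tr <- simulate_training(bp_params(), seed = NULL)
    m <- 100L
    idx <- seq(3 * m, length(tr$y$values), by = m)
    tr$y$values[idx] - tr$x$values[idx]
  })
  truth_var <- stats::var(as.vector(ends))
  tr <- simulate_training(bp_params(), seed = 29)
  est <- estimate_endpoint_variance(tr$x, tr$y)
  n <- 24
  se <- truth_var * sqrt(2 / (n - 1))
  expect_lt(abs(est - truth_var), 3 * se)
})
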