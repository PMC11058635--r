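# shared fixtures and independent oracles, built in code at test time

DT <- 0.05

# the generative spring parameters used by the simulator defaults
true_spring <- function() list(b = 0.375, c = 0.4, delta_t_hat = 0.4)

quick_session <- function(beta = 0.71, walk_seed = 1, agent_seed = 2,
                          params = NULL, ...) {
  if (is.null(params)) params <- bp_params(beta = beta)
  walk <- gen_session_walk(walk_config(seed = walk_seed, ...))
  simulate_session(walk, params, seed = agent_seed)
}

post_idx <- function(session, discard = 10) {
  i0 <- as.integer(floor(discard / session$y$dt)) + 1L
  i0:length(session$y$values)
}

# independent oracle: iterate the scalar Kalman variance recursion to its
# fixed point and return the limiting gain
iterated_gain <- function(process_var, obs_var, n_iter = 10000) {
  P <- obs_var
  k <- NA_real_
  for (i in seq_len(n_iter)) {
    k <- (P + process_var) / (P + process_var + obs_var)
    P <- (1 - k) * (P + process_var)
  }
  k
}

# independent oracle: brute-force sequential Bayes posterior mean on a grid
# for a Gaussian random-walk state observed in Gaussian noise, starting
# from a flat prior over the grid
grid_posterior_means <- function(obs, process_var, obs_var,
                                 grid_half_width = 40, grid_step = 0.01) {
  grid <- seq(obs[1] - grid_half_width, obs[1] + grid_half_width,
              by = grid_step)
  post <- rep(1, length(grid))
  post <- post / sum(post)
  # kernel support symmetric with an odd number of points, otherwise the
  # convolution would drift the posterior by half a grid step per update
  kh <- ceiling(6 * sqrt(process_var) / grid_step)
  kern <- stats::dnorm(seq(-kh, kh) * grid_step, 0, sqrt(process_var))
  kern <- kern / sum(kern)
  means <- numeric(length(obs))
  for (t in seq_along(obs)) {
    if (t > 1L) {
      # diffuse the posterior by the random-walk transition
      post <- stats::convolve(post, rev(kern), type = "open")
      trim <- (length(kern) - 1L) %/% 2L
      post <- post[(trim + 1L):(trim + length(grid))]
      post[post < 0] <- 0
      post <- post / sum(post)
    }
    lik <- stats::dnorm(obs[t], grid, sqrt(obs_var))
    post <- post * lik
    post <- post / sum(post)
    means[t] <- sum(grid * post)
  }
  means
}
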