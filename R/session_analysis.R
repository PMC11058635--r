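#' Constant-gain state estimates from raw session data
#'
#' The first half of the inverse pipeline.  The independent variable is
#' filtered with the gain implied by the world step variance and its sensory
#' noise variance, reproducing the participant's sluggish internal estimate.
#' The dependent variable is filtered with the (small) gain implied by the
#' motor and dependent-channel sensory variances, using the observed
#' increments as the per-step action input: the analysis cannot know the
#' intended actions, so the realised increments (intended action plus motor
#' noise) stand in for them, and the small gain is how the motor noise
#' enters the estimate.  A channel whose observation noise is zero
#' degenerates to gain 1 (the estimate equals the data).
#'
#' @param session a `session_record` (simulated or loaded from file).
#' @param params a [bp_params()] carrying the four variances (typically the
#'   sensory variance comes from the training fit).
#' @return list with `x_hat` and `y_hat` ([angle_series()]) and the gains
#'   `k_x`, `k_y`.
#' @export
estimate_states <- function(session, params) {
  stopifnot(inherits(session, "session_record"),
            inherits(params, "bp_params"))
  gain0 <- function(pv, ov) if (ov == 0) 1 else steady_state_gain(pv, ov)
  k_x <- gain0(params$sigma_mu2, params$sigma_omega2)
  k_y <- gain0(params$sigma_lambda2, params$sigma_psi2)
  xv <- session$x$values
  yv <- session$y$values
  x_hat <- constant_gain_filter(xv, k_x)
  dy <- c(0, diff(yv))
  y_hat <- constant_gain_filter(yv, k_y, input = dy)
  list(x_hat = angle_series(x_hat, session$x$dt, session$x$t0),
       y_hat = angle_series(y_hat, session$y$dt, session$y$t0),
       k_x = k_x, k_y = k_y)
}

default_cutoff_hz <- function(b) {
  # the tracking error of a weakly damped spring has power out to just
  # beyond its resonance, so the smoothing passband extends to 1.6 times
  # the natural frequency sqrt(b)
  1.6 * sqrt(b) / (2 * pi)
}

# exact discrete inverse of the lagged spring difference equation:
# v[t] = (yhat[t] - yhat[t-1])/dt,
# e[t - L] = ((v[t] - v[t-1])/dt + c v[t-1]) / b,  y_tilde = -e.
# The result is indexed at action time; shift_forward() re-aligns it to
# perception time (L samples earlier), holding the last value at the tail.
spring_inverse_raw <- function(yv, b, c, dt) {
  n <- length(yv)
  v <- c(0, diff(yv) / dt)
  v_prev <- c(0, v[-n])
  e <- ((v - v_prev) / dt + c * v_prev) / b
  -e
}

shift_forward <- function(x, L) {
  n <- length(x)
  if (L > 0 && L < n) c(x[(L + 1L):n], rep(x[n], L)) else x
}

#' Invert the action system to recover the perceived deviation
#'
#' Inverts the lagged damped-spring difference equation to recover the
#' error series that drove the participant's actions: the action velocity
#' is the first difference of the dependent estimate, the driving error
#' follows from the spring equation `e[t-lag] = (vdot[t] + c v[t-1]) / b`,
#' and the perceived deviation is `-e`, re-shifted forward by the lag to
#' the time of the perception that caused it.
#'
#' The exact inverse amplifies motor noise quadratically with frequency, so
#' it is smoothed with a zero-phase second-order Butterworth low-pass whose
#' cutoff defaults to 1.6 times the spring's natural frequency
#' (`sqrt(b)/2pi` Hz) — the band in which the action data actually carry
#' information about the error signal.  Above that band the perceived
#' deviation is driven by the stimulus, not resolvable from the action
#' data: when the filtered background series `x_hat` is supplied, the
#' high-band component is reconstructed from the induced-motion prediction
#' `-asin(beta * sin(x_hat))` (coupling strength `beta` estimated in a
#' first pass from the low-band-corrected series when not given) and added
#' to the low-band inverse.
#'
#' @param y_hat dependent-variable estimate ([angle_series()]).
#' @param fit a `spring_fit` (or any list with `b`, `c`, and `delta_t_hat`
#'   or `delta_t`).
#' @param cutoff_hz smoothing cutoff in Hz; `NULL` for the spring-band
#'   default; `Inf` for the raw unsmoothed inverse.
#' @param x_hat optional filtered background [angle_series()] enabling the
#'   stimulus-band reconstruction.
#' @param beta optional coupling strength for the stimulus band.
#' @return the recovered perceived-deviation [angle_series()]; the
#'   first-pass coupling estimate, if computed, is attached as attribute
#'   `"beta_first_pass"`.
#' @export
invert_action <- function(y_hat, fit, cutoff_hz = NULL, x_hat = NULL,
                          beta = NULL) {
  stopifnot(inherits(y_hat, "angle_series"))
  b <- fit$b; c <- fit$c
  lag <- if (!is.null(fit$delta_t_hat)) fit$delta_t_hat else fit$delta_t
  if (!is_scalar(b) || b <= 0)
    stop_fit("invalid spring fit: b must be > 0")
  dt <- y_hat$dt
  if (is.null(cutoff_hz)) cutoff_hz <- default_cutoff_hz(b)
  L <- as.integer(round(lag / dt))
  raw <- spring_inverse_raw(y_hat$values, b, c, dt)
  if (!is.finite(cutoff_hz)) {
    return(angle_series(shift_forward(raw, L), dt, y_hat$t0))
  }
  # smooth at action time first, then re-align: shifting the raw inverse
  # would hold its (noise-dominated) last value across the lag window and
  # leak a large edge transient through the filter
  low <- shift_forward(lowpass_zerophase(raw, cutoff_hz, dt), L)
  beta1 <- NULL
  if (!is.null(x_hat)) {
    stopifnot(inherits(x_hat, "angle_series"))
    if (length(x_hat$values) != length(y_hat$values))
      stop_data("x_hat and y_hat must be equal length")
    if (is.null(beta)) {
      # first pass: coupling strength from the low-band-corrected series
      y_star1 <- y_hat$values - low
      if (stats::sd(y_star1) < 1e-12 || stats::sd(x_hat$values) < 1e-12) {
        beta <- 0
      } else {
        cf <- stats::lm.fit(cbind(1, sind(x_hat$values)), sind(y_star1))
        beta <- unname(cf$coefficients[2L])
      }
      beta1 <- beta
    }
    z <- -asind(clip_unit(beta * sind(x_hat$values)))
    high <- z - lowpass_zerophase(z, cutoff_hz, dt)
    low <- low + high
  }
  out <- angle_series(low, dt, y_hat$t0)
  if (!is.null(beta1)) attr(out, "beta_first_pass") <- beta1
  out
}

residual_lag <- function(x_star, y_star, dt, max_lag_s = 5) {
  sx <- sind(x_star) - mean(sind(x_star))
  sy <- sind(y_star) - mean(sind(y_star))
  if (stats::sd(sx) < 1e-12 || stats::sd(sy) < 1e-12) return(0)
  K <- min(as.integer(round(max_lag_s / dt)), length(sx) - 2L)
  lags <- -K:K
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(sx[1:(length(sx) - l)], sy[(1 + l):length(sy)])
    else stats::cor(sx[(1 - l):length(sx)], sy[1:(length(sy) + l)])
  }, numeric(1))
  lags[which.max(cc)] * dt
}

#' Produce the final "ideal" data series
#'
#' Combines state estimation and action-system inversion into the denoised
#' series: `x_star` is the filtered independent estimate, and `y_star` is
#' the dependent estimate corrected for the recovered perceived deviation
#' from goal (`y_star = y_hat - y_tilde_hat`).  Both are restricted to the
#' post-discard window.  Three lags are reported: the group delay of the
#' independent-variable filter (`dt (1 - k_x) / k_x`), the action-system
#' lag (fitted reaction lag plus the spring's half-rise time), and the
#' residual cross-correlation lag remaining between `x_star` and `y_star`
#' after the first two have been compensated (zero when the model accounts
#' for all lag in the data).
#'
#' @param session a `session_record`.
#' @param params a [bp_params()] with the four noise variances.
#' @param fit a `spring_fit` from the training analysis.
#' @param discard initial seconds excluded from the final series.
#' @param cutoff_hz passed to [invert_action()].
#' @param stimulus_band reconstruct the stimulus-driven high band of the
#'   perceived deviation from the filtered background?
#' @return a `final_series`: list with `x_star`, `y_star`, `y_tilde_hat`
#'   ([angle_series()]), `lag_sense`, `lag_action`, `lag_residual`
#'   (seconds), and the gains `k_x`, `k_y`.
#' @export
finalize <- function(session, params, fit, discard = 10, cutoff_hz = NULL,
                     stimulus_band = TRUE) {
  est <- estimate_states(session, params)
  y_tilde_hat <- invert_action(est$y_hat, fit, cutoff_hz = cutoff_hz,
                               x_hat = if (stimulus_band) est$x_hat)
  i0 <- discard_index(session$y, discard)
  n <- length(session$y$values)
  idx <- i0:n
  dt <- session$y$dt
  t0 <- series_time(session$y)[i0]

  x_star <- est$x_hat$values[idx]
  y_star <- est$y_hat$values[idx] - y_tilde_hat$values[idx]

  lag_sense <- dt * (1 - est$k_x) / est$k_x
  half <- spring_step_response(fit$b, fit$c, 0, dt = dt,
                               duration = 2 * pi / sqrt(fit$b), step = 1)
  t_half <- which(half >= 0.5)
  lag_fit <- if (!is.null(fit$delta_t_hat)) fit$delta_t_hat else fit$delta_t
  lag_action <- lag_fit +
    (if (length(t_half)) t_half[1L] * dt else NA_real_)
  lag_res <- residual_lag(x_star, y_star, dt)

  structure(list(x_star = angle_series(x_star, dt, t0),
                 y_star = angle_series(y_star, dt, t0),
                 y_tilde_hat = angle_series(y_tilde_hat$values[idx], dt, t0),
                 lag_sense = lag_sense, lag_action = lag_action,
                 lag_residual = lag_res,
                 k_x = est$k_x, k_y = est$k_y),
            class = "final_series")
}

#' @export
print.final_series <- function(x, ...) {
  cat(sprintf("<final_series> %d samples at dt = %g s\n",
              length(x$x_star$values), x$x_star$dt))
  cat(sprintf("  lags (s): sense %.3g, action %.3g, residual %.3g\n",
              x$lag_sense, x$lag_action, x$lag_residual))
  cat(sprintf("  gains: k_x = %.4g, k_y = %.4g\n", x$k_x, x$k_y))
  invisible(x)
}
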