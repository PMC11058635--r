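#' Extract aligned, rectified step-response segments from a training session
#'
#' Cuts the target series into one segment per blob step, re-zeroes each
#' segment to the target value immediately before the step, flips the sign
#' of segments driven by anticlockwise blob steps so that every driving
#' step is positive, and truncates each segment at `step_period`.  Epochs
#' beginning inside the initial `discard` window (and the very first epoch,
#' which has no pre-step sample) are excluded.
#'
#' @param blob piecewise-constant blob [angle_series()].
#' @param target participant-driven [angle_series()] on the same grid.
#' @param step_period seconds between blob steps.
#' @param discard initial seconds excluded from analysis.
#' @return list with `segments` (matrix, one column per step), `avg` (the
#'   element-wise average response), `step_size` (mean absolute blob jump,
#'   degrees), `n_steps` and `dt`.
#' @export
extract_step_responses <- function(blob, target, step_period = 5,
                                   discard = 10) {
  stopifnot(inherits(blob, "angle_series"), inherits(target, "angle_series"))
  if (length(blob$values) != length(target$values) ||
      abs(blob$dt - target$dt) > 1e-9)
    stop_data("blob and target series must share grid and length")
  dt <- blob$dt
  m <- step_period / dt
  if (abs(m - round(m)) > 1e-8)
    stop_config("`step_period` is not a multiple of dt")
  m <- as.integer(round(m))
  n <- length(blob$values)
  starts <- seq(1L, n, by = m)
  keep <- starts[starts > 1L & starts + m - 1L <= n &
                   (starts - 1L) * dt >= discard - 1e-9]
  segs <- list(); jumps <- numeric(0)
  for (i0 in keep) {
    jump <- blob$values[i0] - blob$values[i0 - 1L]
    if (abs(jump) < 1e-12) next
    base <- target$values[i0 - 1L]
    seg <- (target$values[i0:(i0 + m - 1L)] - base) * sign(jump)
    segs[[length(segs) + 1L]] <- seg
    jumps <- c(jumps, abs(jump))
  }
  if (length(segs) < 2L)
    stop_data("need at least 2 blob steps after discard; found %d",
              length(segs))
  segments <- do.call(cbind, segs)
  list(segments = segments, avg = rowMeans(segments),
       step_size = mean(jumps), n_steps = length(segs), dt = dt)
}

spring_rss <- function(par, avg, step_size, dt) {
  b <- exp(par[1L]); c <- exp(par[2L]); lag <- par[3L]
  if (!is.finite(b) || !is.finite(c) || lag < 0 || lag > length(avg) * dt)
    return(1e12)
  pred <- spring_step_response(b, c, lag, dt = dt,
                               duration = length(avg) * dt,
                               step = step_size)
  sum((avg - pred)^2)
}

#' Fit the lagged damped-spring model to an averaged step response
#'
#' Least-squares fit of the closed-loop spring difference equation (with a
#' free, linearly interpolated response lag) to an averaged rectified step
#' response.  Optimisation is Nelder-Mead over (log b, log c, lag) from a
#' small multi-start grid, with a polishing restart from the best start.
#' The lag is additionally estimated non-parametrically as the first time
#' the average response departs from baseline by at least 5% of the step
#' size; both estimates are reported.
#'
#' @param avg_response numeric vector: averaged rectified response, sampled
#'   at `dt`, baseline 0, driven by a positive step of `step_size`.
#' @param step_size driving step in degrees.
#' @param dt sampling interval, seconds.
#' @return a `spring_fit`: list with `b`, `c`, `delta_t_hat` (fitted lag),
#'   `delta_t_threshold` (5%-departure lag), `rss`, `n_steps` (filled by
#'   [fit_training()]), `sigma_omega2_hat` (likewise), `dt`.
#' @export
fit_spring <- function(avg_response, step_size, dt) {
  if (length(avg_response) < 10L)
    stop_data("average response too short to fit (need >= 10 samples)")
  if (!is_scalar(step_size) || step_size == 0 ||
      stats::sd(avg_response) < 1e-12)
    stop_fit("no excitation: step size or response variance is zero")

  thr <- 0.05 * abs(step_size)
  dep <- which(abs(avg_response) >= thr)
  delta_thr <- if (length(dep)) dep[1L] * dt else NA_real_

  lag0 <- if (is.finite(delta_thr)) delta_thr else 0.3
  starts <- expand.grid(b = c(0.1, 0.375, 1), c = c(0.01, 0.2, 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(log(starts$b[i]), log(starts$c[i]), lag0)
    fit <- stats::optim(par0, spring_rss, avg = avg_response,
                        step_size = step_size, dt = dt,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the winning start
  best <- stats::optim(best$par, spring_rss, avg = avg_response,
                       step_size = step_size, dt = dt,
                       method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  if (!is.finite(best$value))
    stop_fit("spring fit failed to converge (objective not finite)")

  structure(list(b = exp(best$par[1L]), c = exp(best$par[2L]),
                 delta_t_hat = best$par[3L],
                 delta_t_threshold = delta_thr,
                 rss = best$value, n_steps = NA_integer_,
                 sigma_omega2_hat = NA_real_, dt = dt),
            class = "spring_fit")
}

#' @export
print.spring_fit <- function(x, ...) {
  cat(sprintf("<spring_fit> b = %.4g /s^2, c = %.4g /s\n", x$b, x$c))
  cat(sprintf("  lag: fitted %.3g s, 5%%-threshold %.3g s\n",
              x$delta_t_hat, x$delta_t_threshold))
  cat(sprintf("  rss = %.4g deg^2 over %s steps; sensory var = %.4g deg^2\n",
              x$rss, format(x$n_steps), x$sigma_omega2_hat))
  invisible(x)
}

#' Endpoint variance of the blob-target mismatch
#'
#' Sample variance (n - 1 denominator) of the difference between target and
#' blob at the final sample of each blob step epoch; under the training
#' assumption this estimates the shared sensory noise variance of all three
#' channels.
#'
#' @inheritParams extract_step_responses
#' @return variance in deg^2.
#' @export
estimate_endpoint_variance <- function(blob, target, step_period = 5,
                                       discard = 10) {
  stopifnot(inherits(blob, "angle_series"), inherits(target, "angle_series"))
  dt <- blob$dt
  m <- as.integer(round(step_period / dt))
  n <- length(blob$values)
  starts <- seq(1L, n, by = m)
  ends <- starts + m - 1L
  ok <- ends <= n & (starts - 1L) * dt >= discard - 1e-9
  ends <- ends[ok]
  if (length(ends) < 2L)
    stop_data("need at least 2 complete step epochs after discard")
  stats::var(target$values[ends] - blob$values[ends])
}

#' Estimate participant action-system parameters from a training session
#'
#' Runs the full training analysis: discards the initial window, extracts
#' rectified step responses, averages them, fits the lagged damped-spring
#' model, and estimates the sensory noise variance from the step-end
#' mismatch.
#'
#' @param blob,target blob and target [angle_series()], or a
#'   `session_record` from [simulate_training()] passed as `blob` with
#'   `target = NULL`.
#' @param step_period seconds between blob steps.
#' @param discard initial seconds excluded.
#' @return a `spring_fit` with `n_steps` and `sigma_omega2_hat` filled in.
#' @export
fit_training <- function(blob, target = NULL, step_period = 5,
                         discard = 10) {
  if (inherits(blob, "session_record")) {
    target <- blob$y
    blob <- blob$x
  }
  ex <- extract_step_responses(blob, target, step_period = step_period,
                               discard = discard)
  fit <- fit_spring(ex$avg, ex$step_size, ex$dt)
  fit$n_steps <- ex$n_steps
  fit$sigma_omega2_hat <- estimate_endpoint_variance(
    blob, target, step_period = step_period, discard = discard)
  fit
}
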