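#' Configuration of a computer-driven random direction walk
#'
#' Describes the stimulus random walk driving the independent variable: a
#' Gaussian-step walk over a target angular range, with a buffer outside the
#' range inside which the walk may stray, reflecting boundaries at the
#' buffered limits, and a coverage requirement used when selecting session
#' walks.
#'
#' Defaults reproduce the rightward-quadrant session condition: a 130 s
#' session at 20 updates/s of which the first 10 s are excluded from
#' analysis, a desired range of 0-90 degrees with a 10 degree buffer on
#' either side, and coverage assessed over 9 equal-width bins to match the
#' analysis binning.  The per-step standard deviation `sigma_mu` defaults to
#' 2 degrees, which lets a walk traverse the full quadrant several times
#' within a session so that coverage selection succeeds within a few
#' candidates.
#'
#' @param sigma_mu standard deviation of the Gaussian step, degrees per
#'   update.
#' @param duration total walk duration in seconds.
#' @param dt update interval in seconds.
#' @param range_lo,range_hi desired coverage span in degrees.
#' @param buffer extra range allowed beyond the span on either side,
#'   degrees; reflecting boundaries sit at `range_lo - buffer` and
#'   `range_hi + buffer`.
#' @param discard initial seconds excluded when checking coverage (and later
#'   from analysis).
#' @param n_bins number of equal-width bins over `[range_lo, range_hi]` that
#'   a session walk must visit.
#' @param start starting angle in degrees; defaults to the midpoint of the
#'   range.
#' @param seed optional integer seed recorded in the configuration and used
#'   by the generators.
#' @return a `walk_config` list.
#' @export
walk_config <- function(sigma_mu = 2, duration = 130, dt = 0.05,
                        range_lo = 0, range_hi = 90, buffer = 10,
                        discard = 10, n_bins = 9, start = NULL,
                        seed = NULL) {
  if (!is_scalar(sigma_mu) && !identical(sigma_mu, 0)) {
    if (!(is.numeric(sigma_mu) && length(sigma_mu) == 1L))
      stop_config("`sigma_mu` must be a numeric scalar")
  }
  if (sigma_mu < 0) stop_config("`sigma_mu` must be >= 0")
  if (!is_scalar(dt) || dt <= 0) stop_config("`dt` must be > 0")
  if (!is_scalar(duration) || duration <= 0)
    stop_config("`duration` must be > 0")
  if (!is_scalar(discard) || discard < 0 || duration <= discard)
    stop_config("need duration > discard >= 0 (got %g, %g)",
                duration, discard)
  if (!(range_lo < range_hi)) stop_config("need range_lo < range_hi")
  if (!is_count(n_bins) || n_bins < 1) stop_config("`n_bins` must be >= 1")
  if (is.null(start)) {
    start <- if (is.finite(range_lo) && is.finite(range_hi))
      (range_lo + range_hi) / 2 else 0
  }
  structure(list(sigma_mu = sigma_mu, duration = duration, dt = dt,
                 range_lo = range_lo, range_hi = range_hi, buffer = buffer,
                 discard = discard, n_bins = as.integer(n_bins),
                 start = start, seed = seed),
            class = "walk_config")
}

reflect_into <- function(x, lo, hi) {
  # reflecting boundaries; applied repeatedly in case a step overshoots a
  # boundary by more than the span (only possible for huge steps)
  if (!is.finite(lo) && !is.finite(hi)) return(x)
  for (i in 1:100) {
    if (is.finite(lo) && x < lo) x <- 2 * lo - x
    else if (is.finite(hi) && x > hi) x <- 2 * hi - x
    else return(x)
  }
  stop_data("reflection failed to terminate; step size vastly exceeds range")
}

#' Generate a Gaussian-step random direction walk
#'
#' Each update steps the angle by a draw from N(0, sigma_mu^2).  Steps that
#' would leave the buffered range `[range_lo - buffer, range_hi + buffer]`
#' are reflected at the boundary, which keeps increments zero-mean in the
#' interior without distorting the small-step statistics.
#'
#' @param cfg a [walk_config()].
#' @return an [angle_series()] starting at `cfg$start`; the configuration is
#'   attached as attribute `"config"`.
#' @export
gen_random_walk <- function(cfg) {
  stopifnot(inherits(cfg, "walk_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration / cfg$dt))
  if (n < 1L) stop_config("duration/dt gives an empty walk")
  lo <- cfg$range_lo - cfg$buffer
  hi <- cfg$range_hi + cfg$buffer
  vals <- numeric(n)
  x <- cfg$start
  steps <- if (cfg$sigma_mu > 0) stats::rnorm(n, 0, cfg$sigma_mu)
           else numeric(n)
  for (t in seq_len(n)) {
    x <- reflect_into(x + steps[t], lo, hi)
    vals[t] <- x
  }
  out <- angle_series(vals, cfg$dt, t0 = cfg$dt)
  attr(out, "config") <- cfg
  out
}

coverage_bins_missed <- function(series, cfg) {
  i0 <- discard_index(series, cfg$discard)
  v <- series$values[i0:length(series$values)]
  edges <- seq(cfg$range_lo, cfg$range_hi, length.out = cfg$n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  hit <- tabulate(idx[idx >= 1L & idx <= cfg$n_bins], nbins = cfg$n_bins)
  which(hit == 0L)
}

#' Generate a session walk that covers the desired direction space
#'
#' Repeatedly draws candidate random walks and returns the first whose
#' post-discard segment visits every one of the `n_bins` equal-width bins
#' spanning `[range_lo, range_hi]`.  The number of candidates tried is
#' recorded in attribute `"tries"`.
#'
#' @param cfg a [walk_config()].
#' @param max_tries maximum number of candidate walks.
#' @return a covering [angle_series()].
#' @export
gen_session_walk <- function(cfg, max_tries = 100) {
  stopifnot(inherits(cfg, "walk_config"))
  if (!is_count(max_tries) || max_tries < 1)
    stop_config("`max_tries` must be a positive integer")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL  # candidates drawn from one seeded stream
  missed <- integer(0)
  for (try in seq_len(max_tries)) {
    cand <- gen_random_walk(cfg_inner)
    missed <- coverage_bins_missed(cand, cfg)
    if (length(missed) == 0L) {
      attr(cand, "tries") <- try
      attr(cand, "config") <- cfg
      return(cand)
    }
  }
  stop_data("no covering walk in %d tries; unvisited bins: %s",
            max_tries, paste(missed, collapse = ", "))
}

#' Generate the training-session blob step walk
#'
#' A piecewise-constant walk: at the start of every `step_period` epoch the
#' angle jumps by `step_deg` either clockwise or anticlockwise with equal
#' probability, and stays constant in between.
#'
#' @param step_deg step magnitude in degrees.
#' @param step_period seconds between steps; must be an integer multiple of
#'   `dt`.
#' @param duration total duration in seconds.
#' @param dt update interval in seconds.
#' @param seed optional integer seed.
#' @param start starting angle before the first jump, degrees.
#' @return an [angle_series()]; jump epochs start at samples 1, 1 + m, ...
#'   where `m = step_period/dt`.
#' @export
gen_blob_walk <- function(step_deg = 10, step_period = 5, duration = 130,
                          dt = 0.05, seed = NULL, start = 0) {
  if (!is_scalar(dt) || dt <= 0) stop_config("`dt` must be > 0")
  m <- step_period / dt
  if (abs(m - round(m)) > 1e-8)
    stop_config("`step_period` (%g s) is not an integer multiple of dt (%g s)",
                step_period, dt)
  m <- as.integer(round(m))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration / dt))
  n_epochs <- ceiling(n / m)
  signs <- sample(c(-1, 1), n_epochs, replace = TRUE)
  levels <- start + cumsum(signs * step_deg)
  vals <- rep(levels, each = m)[seq_len(n)]
  out <- angle_series(vals, dt, t0 = dt)
  attr(out, "step_deg") <- step_deg
  attr(out, "step_period") <- step_period
  out
}
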