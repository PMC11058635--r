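#' Uniformly sampled series of direction angles
#'
#' The basic container for all stimulus and response data: a vector of
#' direction angles in degrees, measured clockwise from vertical (vertical =
#' 0, positive = clockwise/rightward), sampled on a uniform time grid.  No
#' angle wrapping is applied; values may transiently exceed +/-90 degrees if
#' a walk configuration permits it.
#'
#' @param values numeric vector of angles in degrees; must be finite.
#' @param dt sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds.
#' @return an object of class `angle_series` with fields `t0`, `dt`,
#'   `values`.
#' @examples
#' s <- angle_series(c(0, 1, 2), dt = 0.05)
#' series_time(s)
#' @export
angle_series <- function(values, dt, t0 = 0) {
  if (!is.numeric(values) || length(values) < 1L)
    stop_data("angle series needs at least one numeric value")
  if (any(!is.finite(values)))
    stop_data("angle series values must all be finite")
  if (!is_scalar(dt) || dt <= 0)
    stop_config("`dt` must be a positive finite scalar (got %s)",
                format(dt[1]))
  if (!is_scalar(t0))
    stop_config("`t0` must be a finite scalar")
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt),
                 values = as.numeric(values)),
            class = "angle_series")
}

#' @export
length.angle_series <- function(x) length(x$values)

#' Sample times of an angle series
#' @param x an `angle_series`.
#' @return numeric vector of times in seconds.
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "angle_series"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples, dt = %g s, t0 = %g s\n",
              length(x$values), x$dt, x$t0))
  cat(sprintf("  range [%.3f, %.3f] deg\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, row.names = NULL, optional = FALSE,
                                       name = "value", ...) {
  out <- data.frame(time = series_time(x), value = x$values)
  names(out)[2] <- name
  out
}

#' Restrict an angle series to a time window
#'
#' @param x an `angle_series`.
#' @param from,to window limits in seconds (inclusive).
#' @return the windowed `angle_series`.
#' @export
window_series <- function(x, from = -Inf, to = Inf) {
  stopifnot(inherits(x, "angle_series"))
  tt <- series_time(x)
  keep <- tt >= from - 1e-9 & tt <= to + 1e-9
  if (!any(keep)) stop_data("window [%g, %g] contains no samples", from, to)
  angle_series(x$values[keep], x$dt, t0 = tt[which(keep)[1L]])
}

# index of the first sample to analyse when the first `discard` seconds of a
# session are excluded
discard_index <- function(x, discard) {
  if (discard <= 0) return(1L)
  min(length(x$values), as.integer(floor(discard / x$dt + 1e-9)) + 1L)
}
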