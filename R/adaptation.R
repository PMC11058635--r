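#' Remove linear-accumulation adaptation from a dependent-variable series
#'
#' The linear adaptation model: prolonged exposure to a net horizontal
#' motion component desensitises the corresponding direction channel in
#' proportion to the accumulated exposure.  For each sample the horizontal
#' speed component `h[t] = speed * sin(y[t])` is corrected to
#' `h[t] - q * S[t]`, where `S` is the running sum of the horizontal
#' components up to and including the current update, and the corrected
#' angle is recovered through the arcsine.  Corrected components whose
#' magnitude exceeds `speed` are clipped; the clip count is attached as
#' attribute `"clipped"`.
#'
#' @param y dependent-variable [angle_series()].
#' @param q adaptation rate per update step (>= 0).
#' @param speed global motion speed, deg/s.
#' @return the corrected [angle_series()].
#' @seealso [re_adapt()] for the exact inverse, [optimize_q()] to estimate
#'   `q`.
#' @export
de_adapt <- function(y, q, speed = 6) {
  stopifnot(inherits(y, "angle_series"))
  if (!is_scalar(q) || q < 0) stop_config("`q` must be >= 0")
  h <- speed * sind(y$values)
  hc <- h - q * cumsum(h)
  hh <- hc / speed
  clipped <- n_clipped(hh)
  out <- angle_series(asind(clip_unit(hh)), y$dt, y$t0)
  attr(out, "clipped") <- clipped
  attr(out, "h_corrected") <- hc
  out
}

#' Re-apply linear-accumulation adaptation
#'
#' Exact inverse of [de_adapt()] in the absence of clipping: reconstructs
#' the original horizontal components from the corrected ones by forward
#' substitution, `h[t] = (hc[t] + q * S[t-1]) / (1 - q)`.
#'
#' @param y_corrected a de-adapted [angle_series()].
#' @inheritParams de_adapt
#' @return the restored [angle_series()].
#' @export
re_adapt <- function(y_corrected, q, speed = 6) {
  stopifnot(inherits(y_corrected, "angle_series"))
  if (!is_scalar(q) || q < 0 || q >= 1) stop_config("`q` must be in [0, 1)")
  hc <- speed * sind(y_corrected$values)
  n <- length(hc)
  h <- numeric(n)
  S <- 0
  for (t in seq_len(n)) {
    h[t] <- (hc[t] + q * S) / (1 - q)
    S <- S + h[t]
  }
  angle_series(asind(clip_unit(h / speed)), y_corrected$dt, y_corrected$t0)
}

intercept_deg <- function(x, y_corr) {
  fit <- stats::lm.fit(cbind(1, sind(x$values)), sind(y_corr$values))
  asind(clip_unit(unname(fit$coefficients[1L])))
}

#' Estimate the adaptation rate from session data
#'
#' One-dimensional bounded minimisation (Brent, via [stats::optimize()]) of
#' the squared difference between a target intercept and the achieved
#' intercept: for a candidate rate `q`, the dependent series is de-adapted,
#' the de-adapted horizontal components are regressed on the background
#' horizontal components, and the regression's y-intercept (converted to
#' degrees) is compared with `target_intercept`.  A target of zero asks for
#' a regression line through the origin; a nonzero target represents a
#' constant perceptual bias.
#'
#' @param x background [angle_series()] (post-discard).
#' @param y dependent [angle_series()] on the same grid.
#' @param target_intercept desired intercept in degrees (default 0).
#' @param speed global motion speed, deg/s.
#' @param q_max upper search bound for `q` (per step).
#' @return an `adaptation_fit`: list with `q`, `target_intercept`,
#'   `achieved_intercept` (degrees), `n_eval`.
#' @export
optimize_q <- function(x, y, target_intercept = 0, speed = 6,
                       q_max = 1e-2) {
  stopifnot(inherits(x, "angle_series"), inherits(y, "angle_series"))
  if (length(x$values) != length(y$values))
    stop_data("x and y series must be aligned and equal length")
  if (stats::sd(y$values) < 1e-9 || stats::sd(x$values) < 1e-9)
    stop_fit("adaptation rate unidentifiable: constant input series")
  n_eval <- 0L
  obj <- function(q) {
    n_eval <<- n_eval + 1L
    (intercept_deg(x, de_adapt(y, q, speed = speed)) - target_intercept)^2
  }
  opt <- stats::optimize(obj, interval = c(0, q_max), tol = 1e-9)
  q_hat <- max(0, opt$minimum)
  # prefer the boundary when it does at least as well: Brent never returns
  # an exact endpoint even when the objective is monotone on the bracket
  if (obj(0) <= opt$objective + 1e-12) q_hat <- 0
  structure(list(q = q_hat, target_intercept = target_intercept,
                 achieved_intercept = intercept_deg(
                   x, de_adapt(y, q_hat, speed = speed)),
                 n_eval = n_eval),
            class = "adaptation_fit")
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("<adaptation_fit> q = %.4g per step\n", x$q))
  cat(sprintf("  intercept: target %.3g deg, achieved %.3g deg (%d evaluations)\n",
              x$target_intercept, x$achieved_intercept, x$n_eval))
  invisible(x)
}
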