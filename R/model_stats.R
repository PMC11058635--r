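#' Bin a dependent series by the value of the independent series
#'
#' Equal-width bins over `[lo, hi]`; independent-variable values straying
#' outside the range (the walk's buffer allows brief excursions) are counted
#' in the nearest edge bin so that every sample contributes.  Per-bin
#' standard deviations use the n - 1 denominator; empty bins carry `NA`
#' mean and SD and a count of 0.
#'
#' @param x,y aligned [angle_series()] (or numeric vectors).
#' @param n_bins number of bins.
#' @param lo,hi bin range in degrees; default to the range of `x`.
#' @return a `bin_summary` data frame with columns `center`, `count`,
#'   `mean`, `sd` and attribute `edges`.
#' @export
bin_series <- function(x, y, n_bins = 9, lo = NULL, hi = NULL) {
  if (inherits(x, "angle_series")) x <- x$values
  if (inherits(y, "angle_series")) y <- y$values
  if (length(x) != length(y)) stop_data("x and y must be equal length")
  if (!is_count(n_bins) || n_bins < 1) stop_config("`n_bins` must be >= 1")
  if (is.null(lo)) lo <- min(x)
  if (is.null(hi)) hi <- max(x)
  if (!(lo < hi)) stop_config("need lo < hi for binning")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(pmin(pmax(x, lo), hi), edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  out <- data.frame(
    center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
    count = tabulate(idx, nbins = n_bins),
    mean = NA_real_, sd = NA_real_)
  for (b in seq_len(n_bins)) {
    yb <- y[idx == b]
    if (length(yb) >= 1L) out$mean[b] <- mean(yb)
    if (length(yb) >= 2L) out$sd[b] <- stats::sd(yb)
  }
  attr(out, "edges") <- edges
  class(out) <- c("bin_summary", "data.frame")
  out
}

#' Fit the induced-motion model to paired direction data
#'
#' Least-squares fit, in horizontal-component space where the model is
#' linear, of `sin(y) = beta * sin(x) + h0`.  The offset is reported both
#' as the unitless horizontal offset `d = -h0` (the constant added to the
#' perceived horizontal component) and as `offset_deg = asin(h0)` in
#' degrees (the y-intercept of the nulling curve, the participant's
#' constant bias).  Fit quality is summarised by R^2 on the raw pairs, by
#' `AIC = n log(RSS/n) + 2K` with K = 3 (slope, offset, error variance; only
#' AIC differences are meaningful), and by the mean square distance in
#' degrees^2 between the per-bin means of `y` and the identically binned
#' means of the model predictions `asin(beta * sin(x) + h0)`, over `n_bins`
#' bins spanning `[lo, hi]`.
#'
#' @param x,y aligned [angle_series()] or numeric vectors of angles,
#'   degrees.
#' @param n_bins,lo,hi binning used for the mean-square-distance statistic;
#'   defaults 9 bins over the range of `x`.
#' @return a `model_fit`: list with `beta`, `d`, `offset_deg`, `r2`, `aic`,
#'   `msd`, `rss`, `n`, and the `bin_summary` used for `msd`.
#' @export
fit_model <- function(x, y, n_bins = 9, lo = NULL, hi = NULL) {
  if (inherits(x, "angle_series")) x <- x$values
  if (inherits(y, "angle_series")) y <- y$values
  if (length(x) != length(y)) stop_data("x and y must be equal length")
  n <- length(x)
  if (n < 3L) stop_data("need at least 3 samples to fit the model")
  sx <- sind(x); sy <- sind(y)
  if (stats::sd(sx) < 1e-12)
    stop_fit("beta unidentifiable: independent variable has zero variance")
  fit <- stats::lm.fit(cbind(1, sx), sy)
  h0 <- unname(fit$coefficients[1L])
  beta <- unname(fit$coefficients[2L])
  rss <- sum(fit$residuals^2)
  tss <- sum((sy - mean(sy))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  aic <- n * log(rss / n) + 2 * 3

  bins <- bin_series(x, y, n_bins = n_bins, lo = lo, hi = hi)
  # per-sample model predictions binned identically to the data, so data
  # lying exactly on the curve give msd = 0
  y_pred <- asind(clip_unit(beta * sx + h0))
  bins_pred <- bin_series(x, y_pred, n_bins = n_bins, lo = lo, hi = hi)
  ok <- !is.na(bins$mean)
  msd <- mean((bins$mean[ok] - bins_pred$mean[ok])^2)

  structure(list(beta = beta, d = -h0,
                 offset_deg = asind(clip_unit(h0)),
                 r2 = r2, aic = aic, msd = msd, rss = rss, n = n,
                 bins = bins),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> beta = %.4g, offset = %.3g deg (d = %.4g)\n",
              x$beta, x$offset_deg, x$d))
  cat(sprintf("  R^2 = %.4g, AIC = %.4g, msd = %.4g deg^2 (n = %d)\n",
              x$r2, x$aic, x$msd, x$n))
  invisible(x)
}

#' Compare a raw and a processed model fit
#'
#' Reports the changes in R^2, AIC, mean square distance and mean per-bin
#' SD between a fit to raw data and a fit to processed data from the same
#' session, and flags an AIC drop of at least 2 as a significant
#' improvement.
#'
#' @param raw,processed `model_fit` objects on the same number of samples.
#' @return a `fit_comparison`: list with `delta_r2`, `delta_aic` (raw minus
#'   processed: positive favours processed), `delta_msd`, `delta_bin_sd`
#'   (both raw minus processed), `mean_bin_sd_raw`,
#'   `mean_bin_sd_processed`, and logical `significant`.
#' @export
compare_fits <- function(raw, processed) {
  stopifnot(inherits(raw, "model_fit"), inherits(processed, "model_fit"))
  if (raw$n != processed$n)
    stop_data("fits compare different sample counts (%d vs %d)",
              raw$n, processed$n)
  sd_raw <- mean(raw$bins$sd, na.rm = TRUE)
  sd_proc <- mean(processed$bins$sd, na.rm = TRUE)
  structure(list(delta_r2 = processed$r2 - raw$r2,
                 delta_aic = raw$aic - processed$aic,
                 delta_msd = raw$msd - processed$msd,
                 delta_bin_sd = sd_raw - sd_proc,
                 mean_bin_sd_raw = sd_raw,
                 mean_bin_sd_processed = sd_proc,
                 significant = (raw$aic - processed$aic) >= 2),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("<fit_comparison> raw -> processed\n")
  cat(sprintf("  delta R^2 = %+.4g, delta AIC = %+.4g (%ssignificant)\n",
              x$delta_r2, x$delta_aic, if (x$significant) "" else "not "))
  cat(sprintf("  delta msd = %+.4g deg^2; mean per-bin SD %.3g -> %.3g deg\n",
              x$delta_msd, x$mean_bin_sd_raw, x$mean_bin_sd_processed))
  invisible(x)
}
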