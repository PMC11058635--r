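# Internal numeric helpers and condition constructors.
#
# Angles are degrees clockwise from vertical throughout; the horizontal
# component of a motion vector at unit speed is sin(angle).

sind <- function(x) sin(x * pi / 180)
asind <- function(x) asin(x) * 180 / pi

# clamp a horizontal component into the representable range before asin
clip_unit <- function(h) pmin(1, pmax(-1, h))

n_clipped <- function(h) sum(h < -1 | h > 1)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# condition classes map onto the CLI exit codes: config = 2, data = 3, fit = 4
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("contpsych_config_error", "contpsych_error",
                                "error", "condition")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("contpsych_data_error", "contpsych_error",
                                "error", "condition")))
}

stop_fit <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("contpsych_fit_error", "contpsych_error",
                                "error", "condition")))
}

# zero-phase second-order Butterworth low-pass (forward-backward pass).
# Both ends are first extended by mirror reflection so the filter
# transients fall on the padding, not the data.  Mirroring (rather than
# point reflection through the endpoint) is deliberate: the inputs are
# noise-dominated, and pivoting the padding on a single extreme endpoint
# sample would shift the whole padded segment by twice that sample.
lowpass_zerophase <- function(x, cutoff_hz, dt) {
  n <- length(x)
  nyq <- 0.5 / dt
  if (cutoff_hz <= 0) stop_config("low-pass cutoff must be > 0")
  if (cutoff_hz >= nyq) return(x)
  bf <- signal::butter(2, cutoff_hz / nyq)
  np <- min(n - 1L, as.integer(round(2 / (cutoff_hz * dt))))
  if (np < 1L) return(x)
  head_pad <- rev(x[2:(np + 1L)])
  tail_pad <- rev(x[(n - np):(n - 1L)])
  padded <- c(head_pad, x, tail_pad)
  signal::filtfilt(bf, padded)[(np + 1L):(np + n)]
}
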