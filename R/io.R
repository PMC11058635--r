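#' Read an angle series from delimited text
#'
#' Expects a comma-separated file with a header whose first column is
#' `time` (seconds) and whose remaining column(s) hold angles in degrees.
#' The time grid must be uniform to within 1e-6 s; a skipped or duplicated
#' sample is reported with its row number.
#'
#' @param path file path.
#' @param column which value column to read (name or index offset from the
#'   time column); default the first value column.
#' @return an [angle_series()].
#' @export
read_series <- function(path, column = NULL) {
  df <- read_timed_table(path)
  if (is.null(column)) column <- names(df)[2L]
  if (is.numeric(column)) column <- names(df)[column + 1L]
  if (!column %in% names(df))
    stop_data("column '%s' not found in %s", column, path)
  angle_series(df[[column]], dt = attr(df, "dt"), t0 = df$time[1L])
}

read_timed_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df) || ncol(df) < 2L)
    stop_data("%s: expected a header starting with 'time' plus value columns",
              path)
  if (nrow(df) < 2L) stop_data("%s: need at least two samples", path)
  dts <- diff(df$time)
  dt <- dts[1L]
  bad <- which(abs(dts - dt) > 1e-6)
  if (length(bad))
    stop_data("%s: non-uniform time grid at row %d (step %.8g, expected %.8g)",
              path, bad[1L] + 2L, dts[bad[1L]], dt)
  attr(df, "dt") <- dt
  df
}

#' Write an angle series as delimited text
#'
#' @param series an [angle_series()].
#' @param path output file path.
#' @param name header name of the value column.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, name = "x") {
  stopifnot(inherits(series, "angle_series"))
  df <- as.data.frame(series, name = name)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a session record as delimited text
#'
#' Columns `time,x,y`, plus the truth columns `x_hat,y_hat,y_tilde,a` when
#' a simulation truth record is present and `truth = TRUE`.
#'
#' @param session a `session_record`.
#' @param path output file path.
#' @param truth include the simulation truth columns if available?
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, truth = FALSE) {
  stopifnot(inherits(session, "session_record"))
  df <- data.frame(time = series_time(session$x),
                   x = session$x$values, y = session$y$values)
  if (truth && !is.null(session$truth)) {
    df$x_hat <- session$truth$x_hat
    df$y_hat <- session$truth$y_hat
    df$y_tilde <- session$truth$y_tilde
    df$a <- session$truth$a
  }
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session record from delimited text
#'
#' @param path a `time,x,y` file as written by [write_session()].
#' @return a `session_record` (without truth or parameters).
#' @export
read_session <- function(path) {
  df <- read_timed_table(path)
  need <- c("x", "y")
  if (!all(need %in% names(df)))
    stop_data("%s: expected columns time,x,y", path)
  dt <- attr(df, "dt")
  structure(list(x = angle_series(df$x, dt, t0 = df$time[1L]),
                 y = angle_series(df$y, dt, t0 = df$time[1L]),
                 truth = NULL, params = NULL, seed = NULL,
                 mode = "correction", k_x = NA_real_, k_y = NA_real_,
                 clipped = NA_integer_),
            class = "session_record")
}

#' Write the final series as delimited text
#'
#' Columns `time,x_star,y_star,y_tilde`.
#'
#' @param final a `final_series` from [finalize()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_final <- function(final, path) {
  stopifnot(inherits(final, "final_series"))
  df <- data.frame(time = series_time(final$x_star),
                   x_star = final$x_star$values,
                   y_star = final$y_star$values,
                   y_tilde = final$y_tilde_hat$values)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
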