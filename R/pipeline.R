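run_config_fields <- c("walk", "params", "analysis", "seed", "out_prefix")
analysis_fields <- c("n_bins", "cutoff_hz", "discard", "deadapt",
                     "target_intercept", "q_max")

#' Full-run configuration
#'
#' Bundles a walk configuration, participant parameters and analysis
#' options for [run_pipeline()], and round-trips losslessly through YAML.
#'
#' @param walk a [walk_config()].
#' @param params a [bp_params()].
#' @param n_bins bins for the model statistics.
#' @param cutoff_hz inversion smoothing cutoff in Hz (`NULL` = spring-band
#'   default).
#' @param discard initial seconds excluded from analysis.
#' @param deadapt estimate and remove linear adaptation before the final
#'   analysis?
#' @param target_intercept target intercept (degrees) for [optimize_q()].
#' @param q_max upper bound of the adaptation-rate search.
#' @param seed master seed for the run.
#' @param out_prefix optional path prefix for written artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(walk = walk_config(), params = bp_params(),
                       n_bins = 9, cutoff_hz = NULL, discard = 10,
                       deadapt = FALSE, target_intercept = 0, q_max = 1e-2,
                       seed = 1, out_prefix = NULL) {
  stopifnot(inherits(walk, "walk_config"), inherits(params, "bp_params"))
  structure(list(walk = walk, params = params,
                 analysis = list(n_bins = n_bins,
                                 cutoff_hz = cutoff_hz,
                                 discard = discard, deadapt = deadapt,
                                 target_intercept = target_intercept,
                                 q_max = q_max),
                 seed = seed, out_prefix = out_prefix),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- list(walk = unclass(cfg$walk), params = unclass(cfg$params),
            analysis = cfg$analysis, seed = cfg$seed,
            out_prefix = cfg$out_prefix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected rather than silently
#' dropped.
#'
#' @param path a YAML file written by [write_run_config()] (or by hand).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), run_config_fields)
  if (length(unknown))
    stop_config("unknown config keys: %s", paste(unknown, collapse = ", "))
  wf <- names(formals(walk_config))
  pf <- names(formals(bp_params))
  uw <- setdiff(names(x$walk), wf)
  if (length(uw)) stop_config("unknown walk keys: %s",
                              paste(uw, collapse = ", "))
  up <- setdiff(names(x$params), pf)
  if (length(up)) stop_config("unknown params keys: %s",
                              paste(up, collapse = ", "))
  ua <- setdiff(names(x$analysis), analysis_fields)
  if (length(ua)) stop_config("unknown analysis keys: %s",
                              paste(ua, collapse = ", "))
  walk <- do.call(walk_config, x$walk[!vapply(x$walk, is.null, TRUE)])
  params <- do.call(bp_params, x$params[!vapply(x$params, is.null, TRUE)])
  a <- x$analysis
  run_config(walk = walk, params = params,
             n_bins = a$n_bins %||% 9,
             cutoff_hz = a$cutoff_hz,
             discard = a$discard %||% 10,
             deadapt = isTRUE(a$deadapt),
             target_intercept = a$target_intercept %||% 0,
             q_max = a$q_max %||% 1e-2,
             seed = x$seed %||% 1, out_prefix = x$out_prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-analyse pipeline
#'
#' End-to-end driver: simulates a training session and fits the spring
#' model; generates a covering session walk and simulates the two-variable
#' session; optionally estimates and removes linear adaptation; produces
#' the final series; and fits and compares the induced-motion model on raw
#' and final data.  All randomness derives from `cfg$seed`.  When
#' `cfg$out_prefix` is set, the session, final series and a YAML report
#' (gains, lags, fits, seeds, clip counts) are written to
#' `<prefix>_session.csv`, `<prefix>_final.csv` and `<prefix>_report.yaml`.
#'
#' @param cfg a [run_config()].
#' @return list with `training_fit`, `session`, `adaptation_fit` (or
#'   `NULL`), `final`, `fit_raw`, `fit_final`, `comparison`, `walk_tries`,
#'   `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  a <- cfg$analysis
  logrec <- list()
  note <- function(stage, ...) {
    logrec[[length(logrec) + 1L]] <<- c(list(stage = stage), list(...))
  }

  training <- simulate_training(cfg$params, dt = cfg$walk$dt,
                                seed = cfg$seed)
  tfit <- fit_training(training, discard = a$discard)
  note("training", b = tfit$b, c = tfit$c, delta_t = tfit$delta_t_hat,
       sigma_omega2 = tfit$sigma_omega2_hat, seed = cfg$seed)

  wcfg <- cfg$walk
  wcfg$seed <- cfg$seed + 1L
  walk <- gen_session_walk(wcfg)
  session <- simulate_session(walk, cfg$params, seed = cfg$seed + 2L)
  note("session", tries = attr(walk, "tries"), k_x = session$k_x,
       k_y = session$k_y, clipped = session$clipped, seed = cfg$seed + 2L)

  i0 <- discard_index(session$y, a$discard)
  idx <- i0:length(session$y$values)
  x_post <- angle_series(session$x$values[idx], session$x$dt)
  y_post <- angle_series(session$y$values[idx], session$y$dt)

  afit <- NULL
  session_an <- session
  if (isTRUE(a$deadapt)) {
    afit <- optimize_q(x_post, y_post,
                       target_intercept = a$target_intercept,
                       q_max = a$q_max)
    y_corr <- de_adapt(session$y, afit$q)
    session_an$y <- y_corr
    note("deadapt", q = afit$q, intercept = afit$achieved_intercept,
         clipped = attr(y_corr, "clipped"))
  }

  final <- finalize(session_an, cfg$params, tfit, discard = a$discard,
                    cutoff_hz = a$cutoff_hz)
  note("finalize", lag_sense = final$lag_sense,
       lag_action = final$lag_action, lag_residual = final$lag_residual)

  lo <- cfg$walk$range_lo; hi <- cfg$walk$range_hi
  fit_raw <- fit_model(session$x$values[idx], session$y$values[idx],
                       n_bins = a$n_bins, lo = lo, hi = hi)
  fit_final <- fit_model(final$x_star, final$y_star,
                         n_bins = a$n_bins, lo = lo, hi = hi)
  comparison <- compare_fits(fit_raw, fit_final)
  note("fit", beta_raw = fit_raw$beta, beta_final = fit_final$beta,
       delta_aic = comparison$delta_aic)

  out <- list(training_fit = tfit, session = session,
              adaptation_fit = afit, final = final,
              fit_raw = fit_raw, fit_final = fit_final,
              comparison = comparison,
              walk_tries = attr(walk, "tries"), log = logrec)

  if (!is.null(cfg$out_prefix)) {
    write_session(session, paste0(cfg$out_prefix, "_session.csv"))
    write_final(final, paste0(cfg$out_prefix, "_final.csv"))
    report <- list(
      seed = cfg$seed,
      training = list(b = tfit$b, c = tfit$c,
                      delta_t = tfit$delta_t_hat,
                      sigma_omega2 = tfit$sigma_omega2_hat),
      gains = list(k_x = final$k_x, k_y = final$k_y),
      lags = list(sense = final$lag_sense, action = final$lag_action,
                  residual = final$lag_residual),
      adaptation = if (is.null(afit)) NULL else
        list(q = afit$q, intercept = afit$achieved_intercept),
      fit_raw = list(beta = fit_raw$beta, offset_deg = fit_raw$offset_deg,
                     r2 = fit_raw$r2, aic = fit_raw$aic, msd = fit_raw$msd),
      fit_final = list(beta = fit_final$beta,
                       offset_deg = fit_final$offset_deg,
                       r2 = fit_final$r2, aic = fit_final$aic,
                       msd = fit_final$msd),
      comparison = list(delta_aic = comparison$delta_aic,
                        delta_bin_sd = comparison$delta_bin_sd,
                        significant = comparison$significant),
      clipped = session$clipped)
    yaml::write_yaml(report, paste0(cfg$out_prefix, "_report.yaml"))
  }
  out
}
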