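# CSV / YAML / JSON interfaces. Column schemas (v1):
#   tracks:  track_id, t_s, x_um, y_um[, z_um]
#   tumbler: cell_id, t_s, psi_rad
#   events:  track_id, t_s, psi_rad, tau_s, prev_class
#   curves:  tau_s, mean_cos, n, se
# All angles are radians, times seconds, positions micrometers.

check_schema <- function(df, required, what, file = NULL) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s%s is missing column(s): %s",
                  what, if (is.null(file)) "" else paste0(" '", file, "'"),
                  paste(missing, collapse = ", ")),
          class = "rotumble_io_error")
  }
  invisible(df)
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' Read and write track tables
#'
#' @param path CSV file path.
#' @param tracks Track tibble (`track_id`, `t_s`, `x_um`, `y_um`, optional
#'   `z_um`), an `rt_simulation`, or an `rt_projection`.
#' @return `read_tracks()` returns a tibble; writers return the path,
#'   invisibly.
#' @name track_io
NULL

#' @rdname track_io
#' @export
read_tracks <- function(path) {
  check_schema(read_csv_quiet(path), c("track_id", "t_s", "x_um", "y_um"),
               "tracks file", path)
}

#' @rdname track_io
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "rt_simulation")) tracks <- tracks$tracks
  if (inherits(tracks, "rt_projection")) tracks <- tracks$tracks
  check_schema(tracks, c("track_id", "t_s", "x_um", "y_um"), "tracks table")
  readr::write_csv(tracks, path)
  invisible(path)
}

#' Read and write reorientation-event tables
#'
#' @param path CSV file path.
#' @param events Event tibble (`track_id`, `t_start`, `psi`, `tau`,
#'   `prev_class`).
#' @return `read_events()` returns a tibble in the internal layout.
#' @name event_io
NULL

#' @rdname event_io
#' @export
read_events <- function(path) {
  df <- check_schema(read_csv_quiet(path),
                     c("track_id", "t_s", "psi_rad", "tau_s", "prev_class"),
                     "events file", path)
  tibble::tibble(track_id = df$track_id, t_start = df$t_s, psi = df$psi_rad,
                 tau = df$tau_s, prev_class = df$prev_class)
}

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  check_schema(events, c("track_id", "t_start", "psi", "tau", "prev_class"),
               "events table")
  readr::write_csv(
    tibble::tibble(track_id = events$track_id, t_s = events$t_start,
                   psi_rad = events$psi, tau_s = events$tau,
                   prev_class = events$prev_class),
    path)
  invisible(path)
}

#' Read and write correlation curves
#'
#' @param path CSV file path.
#' @param curve An `rt_curve` tibble.
#' @return `read_curve()` returns an `rt_curve`.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
read_curve <- function(path) {
  df <- check_schema(read_csv_quiet(path), c("tau_s", "mean_cos", "n", "se"),
                     "curve file", path)
  out <- tibble::tibble(tau = df$tau_s, mean_cos = df$mean_cos, n = df$n,
                        se = df$se)
  class(out) <- c("rt_curve", class(out))
  attr(out, "bin_width") <- if (nrow(out) > 1L) min(diff(sort(out$tau))) else 0.1
  attr(out, "min_count") <- min(out$n)
  out
}

#' @rdname curve_io
#' @export
write_curve <- function(curve, path) {
  check_schema(curve, c("tau", "mean_cos", "n", "se"), "curve table")
  readr::write_csv(
    tibble::tibble(tau_s = curve$tau, mean_cos = curve$mean_cos,
                   n = curve$n, se = curve$se),
    path)
  invisible(path)
}

#' Read and write tumbler orientation series
#'
#' @param path CSV file path.
#' @param series Tibble `cell_id`, `t_s`, `psi_rad`.
#' @name tumbler_io
NULL

#' @rdname tumbler_io
#' @export
read_tumbler_series <- function(path) {
  check_schema(read_csv_quiet(path), c("cell_id", "t_s", "psi_rad"),
               "tumbler file", path)
}

#' @rdname tumbler_io
#' @export
write_tumbler_series <- function(series, path) {
  check_schema(series, c("cell_id", "t_s", "psi_rad"), "tumbler table")
  readr::write_csv(series, path)
  invisible(path)
}

#' Scenario configuration files
#'
#' Scenarios serialize to a flat YAML mapping that round-trips losslessly;
#' `tumble_*` keys describe the [tumble_time_model()] and `d_r_up` /
#' `d_r_perp` / `d_r_down` the optional per-class coefficients.
#'
#' @param scenario An `rt_scenario`.
#' @param path YAML file path.
#' @name scenario_io
NULL

#' @rdname scenario_io
#' @export
scenario_to_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "rt_scenario"))
  cfg <- list(
    v_run = scenario$v_run, mean_run = scenario$mean_run,
    tumble_kind = scenario$tumble_model$kind,
    tumble_mean = scenario$tumble_model$mean,
    tumble_step = scenario$tumble_model$step,
    d_r = scenario$d_r, frame_rate = scenario$frame_rate,
    duration = scenario$duration, n_tracks = scenario$n_tracks,
    gradient_axis = scenario$gradient_axis,
    chi_run = scenario$chi_run, chi_tumble = scenario$chi_tumble,
    d_r_up = scenario$d_r_by_class[["up"]],
    d_r_perp = scenario$d_r_by_class[["perp"]],
    d_r_down = scenario$d_r_by_class[["down"]],
    mode = scenario$mode, seed = scenario$seed
  )
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1L))], path)
  invisible(path)
}

#' @rdname scenario_io
#' @export
scenario_from_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("malformed config '%s': %s", path, conditionMessage(e)),
          class = "rotumble_io_error")
  })
  need <- c("v_run", "mean_run", "tumble_kind", "tumble_mean", "d_r",
            "frame_rate", "duration", "n_tracks", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    abort(sprintf("config '%s' is missing key(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "rotumble_io_error")
  }
  model <- tumble_time_model(cfg$tumble_kind, cfg$tumble_mean,
                             cfg$tumble_step)
  by_class <- NULL
  if (!is.null(cfg$d_r_up)) {
    by_class <- list(up = cfg$d_r_up, perp = cfg$d_r_perp,
                     down = cfg$d_r_down)
  }
  run_tumble_scenario(
    v_run = cfg$v_run, mean_run = cfg$mean_run, tumble_model = model,
    d_r = cfg$d_r, frame_rate = cfg$frame_rate, duration = cfg$duration,
    n_tracks = cfg$n_tracks,
    gradient_axis = if (is.null(cfg$gradient_axis)) NULL else
      as.numeric(cfg$gradient_axis),
    chi_run = cfg$chi_run %||% 0, chi_tumble = cfg$chi_tumble %||% 0,
    d_r_by_class = by_class, mode = cfg$mode %||% "planar", seed = cfg$seed
  )
}

#' Write a fit report as JSON
#'
#' @param fit A `dr_fit` or `rt_class_fits` object.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  payload <- if (inherits(fit, "dr_fit")) {
    list(method = fit$method, d_r_hat = fit$d_r_hat, stderr = fit$stderr,
         n_points = fit$n_points, objective = fit$objective,
         converged = fit$converged, flagged = fit$flagged)
  } else if (inherits(fit, "rt_class_fits")) {
    list(classes = as.data.frame(fit),
         homogeneous = attr(fit, "homogeneous"))
  } else {
    abort("`fit` must be a dr_fit or rt_class_fits.",
          class = "rotumble_parameter_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
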