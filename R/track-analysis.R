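# Turning 2D tracks into runs, tumbles, reorientation events and
# correlation curves.
#
# Frame intervals are labeled "tumble" when the instantaneous speed drops
# below a fraction of the track's median speed OR the frame-to-frame turn
# rate exceeds a threshold; short runs are merged into the neighboring
# tumbles. The detection criteria of published tracking pipelines are
# unpublished, so the thresholds are exposed and their defaults documented
# against the simulator (see the methods vignette).

#' Segment a 2D track into runs and tumbles
#'
#' @param track Tibble with columns `t_s`, `x_um`, `y_um` (one track,
#'   uniformly sampled, at least 10 frames).
#' @param speed_factor Tumble speed threshold as a fraction of the track's
#'   median frame speed.
#' @param turn_rate_thresh Tumble turn-rate threshold, rad/s.
#' @param min_run_frames Runs spanning fewer frame intervals than this are
#'   merged into the neighboring tumbles.
#' @return A tibble of class `rt_segments` with columns `kind`, `t_start`,
#'   `t_end`, `duration`, `dir_x`, `dir_y` (mean run direction, unit vector;
#'   `NA` for tumbles).
#' @examples
#' tr <- tibble::tibble(t_s = seq(0, 2, 0.1), x_um = seq(0, 40, 2), y_um = 0)
#' segment_track(tr)
#' @export
segment_track <- function(track, speed_factor = 0.5, turn_rate_thresh = 5,
                          min_run_frames = 1L) {
  need <- c("t_s", "x_um", "y_um")
  if (!all(need %in% names(track))) {
    abort("track needs columns t_s, x_um, y_um.",
          class = "rotumble_parameter_error")
  }
  if (nrow(track) < 10L) {
    abort("track shorter than 10 frames; skipped.",
          class = "rotumble_short_track")
  }
  dt_all <- diff(track$t_s)
  if (any(dt_all <= 0)) {
    abort("frame times must be strictly increasing.",
          class = "rotumble_domain_error")
  }
  dt <- median(dt_all)
  if (max(abs(dt_all - dt)) > 1e-6 * max(dt, 1e-12)) {
    abort("track must be uniformly sampled.", class = "rotumble_domain_error")
  }
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  speed <- sqrt(dx^2 + dy^2) / dt
  med <- median(speed)
  ang <- atan2(dy, dx)
  boundary_turn <- abs(wrap_angle(diff(ang))) / dt # between intervals i, i+1
  boundary_turn[speed[-length(speed)] == 0 | speed[-1L] == 0] <- 0
  lab <- speed < speed_factor * med
  # attribute each turning boundary to the slower of its two intervals:
  # the reorientation happens while the cell is (partly) paused
  hot <- which(boundary_turn > turn_rate_thresh)
  slower <- hot + (speed[hot + 1L] < speed[hot])
  lab[slower] <- TRUE

  # merge short runs into neighboring tumbles
  r <- rle(lab)
  short_run <- !r$values & r$lengths < min_run_frames
  if (any(!short_run & !r$values)) { # never erase the only run of a track
    r$values[short_run] <- TRUE
    lab <- inverse.rle(r)
  }

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- purrr::map_dfr(seq_along(r$values), function(i) {
    ii <- starts[i]:ends[i] # interval indices
    sx <- sum(dx[ii]); sy <- sum(dy[ii])
    nrm <- sqrt(sx^2 + sy^2)
    tibble::tibble(
      kind = if (r$values[i]) "tumble" else "run",
      t_start = track$t_s[starts[i]],
      t_end = track$t_s[ends[i] + 1L],
      duration = r$lengths[i] * dt,
      dir_x = if (!r$values[i] && nrm > 1e-12) sx / nrm else NA_real_,
      dir_y = if (!r$values[i] && nrm > 1e-12) sy / nrm else NA_real_
    )
  })
  class(segs) <- c("rt_segments", class(segs))
  attr(segs, "dt") <- dt
  attr(segs, "params") <- list(speed_factor = speed_factor,
                               turn_rate_thresh = turn_rate_thresh,
                               min_run_frames = min_run_frames)
  segs
}

#' Segment many tracks
#'
#' Applies [segment_track()] per `track_id`; tracks that are too short are
#' skipped with a message.
#'
#' @param tracks Tibble with columns `track_id`, `t_s`, `x_um`, `y_um` (or
#'   an `rt_projection` whose `tracks` element has them).
#' @inheritParams segment_track
#' @return Combined `rt_segments` tibble with a `track_id` column.
#' @export
segment_tracks <- function(tracks, speed_factor = 0.5, turn_rate_thresh = 5,
                           min_run_frames = 1L) {
  if (inherits(tracks, "rt_projection")) tracks <- tracks$tracks
  n_skip <- 0L
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(df, key) {
      seg <- tryCatch(
        segment_track(df, speed_factor, turn_rate_thresh, min_run_frames),
        rotumble_short_track = function(e) NULL
      )
      if (is.null(seg)) {
        n_skip <<- n_skip + 1L
        return(NULL)
      }
      dplyr::mutate(seg, track_id = key$track_id, .before = 1L)
    }) |>
    dplyr::bind_rows()
  if (n_skip > 0L) inform(sprintf("%d track(s) skipped (too short).", n_skip))
  class(out) <- c("rt_segments", class(out))
  out
}

#' Extract reorientation events from segmented tracks
#'
#' For every tumble flanked by two runs of the same track, measures the
#' projected reorientation angle \eqn{\psi} between the mean directions of
#' the two runs, the tumble duration \eqn{\tau}, and the quadrant class of
#' the preceding run relative to the gradient axis: half-open cones of
#' `cone_half_angle` degrees about the axis give `up` / `down` (the boundary
#' belongs to `perp`), the two perpendicular quadrants are merged.
#'
#' @param segments Output of [segment_track()] or [segment_tracks()].
#' @param gradient_axis Unit 2D vector, or `NULL` for no classification
#'   (class `"none"`).
#' @param cone_half_angle Half-angle of the up/down cones, degrees.
#' @return Tibble with columns `track_id`, `t_start`, `psi` (rad, in
#'   \eqn{[0, \pi]}), `tau` (s) and `prev_class`.
#' @export
reorientation_events <- function(segments, gradient_axis = NULL,
                                 cone_half_angle = 45) {
  if (!inherits(segments, "rt_segments")) {
    abort("`segments` must come from segment_track(s).",
          class = "rotumble_parameter_error")
  }
  if (!"track_id" %in% names(segments)) {
    segments <- dplyr::mutate(segments, track_id = 1L, .before = 1L)
  }
  segments |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 3L) return(NULL)
      i <- which(df$kind == "tumble")
      i <- i[i > 1L & i < nrow(df)]
      i <- i[df$kind[i - 1L] == "run" & df$kind[i + 1L] == "run"]
      if (length(i) == 0L) return(NULL)
      ok <- !is.na(df$dir_x[i - 1L]) & !is.na(df$dir_x[i + 1L])
      if (any(!ok)) {
        inform(sprintf("%d event(s) dropped (zero-length run direction).",
                       sum(!ok)))
        i <- i[ok]
      }
      if (length(i) == 0L) return(NULL)
      psi <- angle_between_2d(df$dir_x[i - 1L], df$dir_y[i - 1L],
                              df$dir_x[i + 1L], df$dir_y[i + 1L])
      cls <- if (is.null(gradient_axis)) {
        rep("none", length(i))
      } else {
        classify_direction_2d(df$dir_x[i - 1L], df$dir_y[i - 1L],
                              gradient_axis, cone_half_angle)
      }
      tibble::tibble(track_id = key$track_id, t_start = df$t_start[i],
                     psi = psi, tau = df$duration[i], prev_class = cls)
    }) |>
    dplyr::bind_rows()
}

#' Bin reorientation events into a correlation curve
#'
#' Events are binned by tumble duration (bins centered on multiples of
#' `bin_width`, matching the time quantum of frame-limited tumble
#' durations); each reported bin carries the mean cosine of \eqn{\psi}, the
#' event count and the standard error of the mean. Bins with fewer than
#' `min_count` events are suppressed.
#'
#' @param events Tibble with columns `psi` and `tau` (e.g. from
#'   [reorientation_events()] or [true_events()]).
#' @param bin_width Duration bin width, s.
#' @param min_count Minimum events per reported bin.
#' @return A tibble of class `rt_curve` with columns `tau`, `mean_cos`, `n`,
#'   `se`.
#' @export
correlation_curve <- function(events, bin_width = 0.1, min_count = 10L) {
  if (!all(c("psi", "tau") %in% names(events))) {
    abort("`events` must have columns psi and tau.",
          class = "rotumble_parameter_error")
  }
  if (nrow(events) < min_count) {
    abort("fewer events than `min_count`.", class = "rotumble_parameter_error")
  }
  out <- events |>
    dplyr::mutate(bin = round(.data$tau / bin_width)) |>
    dplyr::filter(.data$bin > 0) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      tau = .data$bin[1L] * bin_width,
      mean_cos = mean(cos(.data$psi)),
      n = dplyr::n(),
      se = sd(cos(.data$psi)) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_count) |>
    dplyr::arrange(.data$tau) |>
    dplyr::select("tau", "mean_cos", "n", "se")
  if (nrow(out) == 0L) {
    abort("no duration bin reaches `min_count` events.",
          class = "rotumble_parameter_error")
  }
  class(out) <- c("rt_curve", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "min_count") <- min_count
  out
}

#' Orientation autocorrelation of tumbler series
#'
#' \eqn{\langle\cos(\psi(t+\tau) - \psi(t))\rangle} of the unwrapped planar
#' body-axis angle, averaged over all valid frame pairs and all cells, for
#' every lag multiple of the frame interval up to `max_lag`. Standard errors
#' are computed by per-cell blocking (standard deviation of the per-cell
#' means across cells); with fewer than 2 cells the SE is `NA`.
#'
#' @param series Tibble from [simulate_tumbler()] (columns `cell_id`, `t_s`,
#'   `psi_rad`, uniform sampling).
#' @param max_lag Largest lag, s; must be smaller than the series span.
#' @return An `rt_curve` tibble (`tau`, `mean_cos`, `n`, `se`).
#' @export
orientation_autocorrelation <- function(series, max_lag) {
  need <- c("cell_id", "t_s", "psi_rad")
  if (!all(need %in% names(series))) {
    abort("series needs columns cell_id, t_s, psi_rad.",
          class = "rotumble_parameter_error")
  }
  cells <- split(series, series$cell_id)
  dt <- median(diff(cells[[1L]]$t_s))
  span <- diff(range(cells[[1L]]$t_s))
  if (max_lag >= span) {
    abort("`max_lag` must be smaller than the series span.",
          class = "rotumble_parameter_error")
  }
  lags <- seq_len(floor(max_lag / dt))
  per_cell <- purrr::map(cells, function(df) {
    psi <- df$psi_rad
    vapply(lags, function(L) {
      n <- length(psi) - L
      c(mean(cos(psi[(1L + L):(n + L)] - psi[1:n])), n)
    }, numeric(2L))
  })
  mc <- vapply(per_cell, function(m) m[1L, ], numeric(length(lags)))
  ns <- vapply(per_cell, function(m) m[2L, ], numeric(length(lags)))
  mc <- matrix(mc, nrow = length(lags))
  ns <- matrix(ns, nrow = length(lags))
  out <- tibble::tibble(
    tau = lags * dt,
    mean_cos = rowSums(mc * ns) / rowSums(ns),
    n = as.integer(rowSums(ns)),
    se = if (length(cells) >= 2L) {
      apply(mc, 1L, sd) / sqrt(length(cells))
    } else {
      NA_real_
    }
  )
  class(out) <- c("rt_curve", class(out))
  attr(out, "bin_width") <- dt
  attr(out, "min_count") <- 1L
  out
}

#' @method autoplot rt_curve
#' @export
autoplot.rt_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$mean_cos)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_cos - .data$se,
                                          ymax = .data$mean_cos + .data$se),
                             ...) +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression("<cos" ~ psi * ">"),
                  title = "Projected directional correlation")
  if (!is.null(fit) && inherits(fit, "dr_fit")) {
    tt <- seq(0, max(object$tau), length.out = 200L)
    rate <- fit$details$rate %||% fit$d_r_hat
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(tau = tt, mean_cos = exp(-rate * tt)),
      colour = "firebrick"
    )
  }
  p
}

#' Quick-look plot of 2D tracks
#'
#' @param tracks Tibble with `track_id`, `x_um`, `y_um` (or an
#'   `rt_projection`).
#' @param max_tracks Number of tracks to draw.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, max_tracks = 20L) {
  if (inherits(tracks, "rt_projection")) tracks <- tracks$tracks
  ids <- unique(tracks$track_id)
  keep <- ids[seq_len(min(length(ids), max_tracks))]
  df <- dplyr::filter(tracks, .data$track_id %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   group = .data$track_id,
                                   colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}
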