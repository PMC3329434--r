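# Chemotactic drift and persistence arithmetic.

#' Translational diffusion coefficient of a persistent run-and-tumble walk
#'
#' Lovely-Dahlquist closure for the long-time active translational diffusion
#' coefficient of a run-and-tumble walker with speed `v_run`, mean run
#' duration `mean_run` and directional persistence `alpha` (mean cosine of
#' the reorientation between successive runs):
#' \deqn{D_t = v^2 \bar\tau_{run} / (d (1 - \alpha))}
#' with `d` the spatial dimension (3 by default). At `alpha = 0` this is the
#' classic non-persistent value \eqn{v^2 \bar\tau_{run} / d}; persistence
#' amplifies it by \eqn{1/(1-\alpha)}. The closure neglects the time spent
#' in tumbles (a ~12% effect at the canonical run/tumble duty cycle) and
#' assumes exponential run durations.
#'
#' @param v_run Run speed, um/s.
#' @param mean_run Mean run duration, s.
#' @param alpha Persistence factor, \eqn{< 1} (see
#'   [persistence_from_rotdiff()]).
#' @param dimension Spatial dimension (3 for free swimming, 2 for planar
#'   walks).
#' @return Translational diffusion coefficient, um^2/s.
#' @examples
#' translational_diffusion(20, 1, alpha = 0.33)
#' @export
translational_diffusion <- function(v_run, mean_run, alpha, dimension = 3) {
  check_positive_scalar(v_run, "v_run")
  check_positive_scalar(mean_run, "mean_run")
  if (!is.numeric(alpha) || alpha >= 1) {
    abort("`alpha` must be < 1.", class = "rotumble_domain_error")
  }
  v_run^2 * mean_run / (dimension * (1 - alpha))
}

#' Chemotactic drift velocity
#'
#' Mean velocity component along the gradient axis: per-track net
#' displacement along the axis divided by the track duration, averaged over
#' tracks, with the standard error across tracks.
#'
#' @param tracks Frame-sampled track tibble (`track_id`, `t_s`, `x_um`,
#'   `y_um`), an `rt_simulation`, or an `rt_projection`; at least 10 tracks.
#' @param gradient_axis Unit 2D vector along which drift is measured.
#' @return One-row tibble with `v_drift` (um/s), `se` and `n_tracks`.
#' @export
drift_velocity <- function(tracks, gradient_axis) {
  if (inherits(tracks, "rt_simulation")) tracks <- tracks$tracks
  if (inherits(tracks, "rt_projection")) tracks <- tracks$tracks
  if (is.null(gradient_axis) || length(gradient_axis) < 2L) {
    abort("`gradient_axis` must be a 2D vector.",
          class = "rotumble_parameter_error")
  }
  gradient_axis <- gradient_axis / sqrt(sum(gradient_axis^2))
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      v = (( dplyr::last(.data$x_um) - dplyr::first(.data$x_um)) * gradient_axis[1L] +
           ( dplyr::last(.data$y_um) - dplyr::first(.data$y_um)) * gradient_axis[2L]) /
        (dplyr::last(.data$t_s) - dplyr::first(.data$t_s)),
      .groups = "drop"
    )
  if (nrow(per) < 10L) {
    abort("need at least 10 tracks.", class = "rotumble_parameter_error")
  }
  tibble::tibble(v_drift = mean(per$v), se = sd(per$v) / sqrt(nrow(per)),
                 n_tracks = nrow(per))
}

#' Up/down modulation summary
#'
#' Relative modulation of the per-class rotational diffusion coefficient and
#' of the mean tumble duration between runs down and up the gradient axis,
#' \eqn{(X_{down} - X_{up}) / X_{baseline}}. Because the baseline convention
#' of such percentages is ambiguous, all three candidates are reported:
#' the mean of the two classes (default headline), the perpendicular class,
#' and the grand (pooled) value.
#'
#' @param class_fits Output of [fit_by_class()] (must contain `up` and
#'   `down` rows).
#' @param events Event tibble with `tau` and `prev_class`, used for the
#'   tumble-duration modulation.
#' @return Tibble with columns `quantity`, `down`, `up`, `baseline_kind`,
#'   `baseline`, `relative_modulation`.
#' @export
modulation_summary <- function(class_fits, events) {
  need <- c("up", "down")
  if (!all(need %in% class_fits$class)) {
    abort("`class_fits` must contain both 'up' and 'down' classes.",
          class = "rotumble_parameter_error")
  }
  val <- function(cl) class_fits$d_r_hat[class_fits$class == cl][1L]
  taus <- events |>
    dplyr::group_by(.data$prev_class) |>
    dplyr::summarise(mean_tau = mean(.data$tau), .groups = "drop")
  tau_of <- function(cl) taus$mean_tau[taus$prev_class == cl][1L]
  rows <- list(
    list(quantity = "d_r", down = val("down"), up = val("up"),
         perp = if ("perp" %in% class_fits$class) val("perp") else NA_real_,
         pooled = if ("pooled" %in% class_fits$class) val("pooled") else NA_real_),
    list(quantity = "mean_tau_tumble", down = tau_of("down"), up = tau_of("up"),
         perp = if ("perp" %in% taus$prev_class) tau_of("perp") else NA_real_,
         pooled = mean(events$tau))
  )
  purrr::map_dfr(rows, function(r) {
    delta <- r$down - r$up
    tibble::tibble(
      quantity = r$quantity, down = r$down, up = r$up,
      baseline_kind = c("class_mean", "perp", "grand_mean"),
      baseline = c(mean(c(r$down, r$up)), r$perp, r$pooled),
      relative_modulation = delta / c(mean(c(r$down, r$up)), r$perp, r$pooled)
    )
  })
}
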