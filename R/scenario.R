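# Generative scenarios for synthetic run-and-tumble experiments.

#' Run-and-tumble scenario
#'
#' Full generative parameter set for synthetic trajectories: straight runs at
#' constant speed with exponential durations, tumbles with durations from a
#' [tumble_time_model()] and reorientation by rotational diffusion, optional
#' chemotactic modulation, and camera sampling at a fixed frame rate.
#'
#' Modulation is cosine-linear in the angle \eqn{\varphi} between the
#' swimming direction and the gradient axis: run durations have mean
#' \eqn{\bar\tau_{run} (1 + \chi_{run} \cos\varphi)} and tumble durations
#' mean \eqn{\bar\tau_{tum} (1 - \chi_{tum} \cos\varphi)}, so runs up the
#' gradient lengthen and the tumbles that follow them shorten. In the wave
#' regime the rotational diffusion coefficient itself can depend on the
#' direction class of the preceding run via `d_r_by_class`.
#'
#' Two generative modes are provided. The default `mode = "planar"` is the
#' observation-plane model used for all tracking analyses: positions and
#' headings live in the plane (z = 0), each tumble applies the planar
#' reorientation \eqn{\psi \sim N(0, 2 D_r \tau)} (wrapped) while the latent
#' 3D reorientation angle \eqn{\theta} is recorded as ground truth.
#' `mode = "3d"` generates fully three-dimensional headings with exact
#' spherical reorientations, for properties that need 3D isotropy.
#'
#' @param v_run Run speed, um/s.
#' @param mean_run Mean run duration, s.
#' @param tumble_model A [tumble_time_model()].
#' @param d_r Rotational diffusion coefficient during tumbles, rad^2/s.
#' @param frame_rate Camera frame rate, Hz.
#' @param duration Track duration, s.
#' @param n_tracks Number of tracks.
#' @param gradient_axis Unit 2D vector of the gradient / wave axis, or `NULL`.
#' @param chi_run,chi_tumble Modulation amplitudes in \eqn{[0, 1)}.
#' @param d_r_by_class Optional named list/vector with entries `up`, `down`,
#'   `perp` overriding `d_r` per direction class of the preceding run.
#' @param mode `"planar"` (default) or `"3d"`.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return An object of class `rt_scenario`.
#' @seealso [simulate_run_tumble()], [scenario_homogeneous()]
#' @export
run_tumble_scenario <- function(v_run = 20, mean_run = 1,
                                tumble_model = tumble_time_model(
                                  "discrete_exponential", 0.14, 0.1),
                                d_r = 2.1, frame_rate = 10, duration = 20,
                                n_tracks = 100, gradient_axis = NULL,
                                chi_run = 0, chi_tumble = 0,
                                d_r_by_class = NULL,
                                mode = c("planar", "3d"), seed = 1L) {
  mode <- match.arg(mode)
  check_positive_scalar(v_run, "v_run")
  check_positive_scalar(mean_run, "mean_run")
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  check_positive_scalar(frame_rate, "frame_rate")
  check_positive_scalar(duration, "duration")
  stopifnot(inherits(tumble_model, "tumble_time_model"))
  if (n_tracks < 1) {
    abort("`n_tracks` must be >= 1.", class = "rotumble_parameter_error")
  }
  for (chi in c(chi_run, chi_tumble)) {
    if (chi < 0 || chi >= 1) {
      abort("modulation amplitudes must lie in [0, 1).",
            class = "rotumble_parameter_error")
    }
  }
  if (!is.null(gradient_axis)) {
    gradient_axis <- gradient_axis / sqrt(sum(gradient_axis^2))
  }
  # worst-case modulated tumble mean must stay valid
  if (chi_tumble > 0 && tumble_model$kind == "discrete_exponential") {
    if (tumble_model$mean * (1 - chi_tumble) <= tumble_model$step) {
      abort(paste0("tumble modulation drives the discrete mean at or below ",
                   "the step; reduce `chi_tumble`."),
            class = "rotumble_parameter_error")
    }
  }
  if (!is.null(d_r_by_class)) {
    if (!all(c("up", "down", "perp") %in% names(d_r_by_class))) {
      abort("`d_r_by_class` needs entries up, down, perp.",
            class = "rotumble_parameter_error")
    }
  }
  structure(
    list(v_run = v_run, mean_run = mean_run, tumble_model = tumble_model,
         d_r = d_r, frame_rate = frame_rate, duration = duration,
         n_tracks = as.integer(n_tracks), gradient_axis = gradient_axis,
         chi_run = chi_run, chi_tumble = chi_tumble,
         d_r_by_class = d_r_by_class, mode = mode, seed = as.integer(seed)),
    class = "rt_scenario"
  )
}

#' @export
print.rt_scenario <- function(x, ...) {
  cat(sprintf(
    "<rt_scenario> %s: %d tracks x %g s, v = %g um/s, <run> = %g s, D_r = %g rad^2/s\n",
    x$mode, x$n_tracks, x$duration, x$v_run, x$mean_run, x$d_r))
  if (!is.null(x$gradient_axis)) {
    cat(sprintf("  gradient axis (%.2f, %.2f), chi_run = %g, chi_tumble = %g\n",
                x$gradient_axis[1L], x$gradient_axis[2L], x$chi_run,
                x$chi_tumble))
  }
  if (!is.null(x$d_r_by_class)) {
    cat(sprintf("  D_r by class: up %g, perp %g, down %g\n",
                x$d_r_by_class[["up"]], x$d_r_by_class[["perp"]],
                x$d_r_by_class[["down"]]))
  }
  invisible(x)
}

#' Reference scenarios
#'
#' Packaged study conditions for the three tracking regimes: swimming in
#' homogeneous motility buffer (`scenario_homogeneous`, D_r = 2.1 rad^2/s),
#' a shallow static nutrient gradient (`scenario_gradient`, single
#' D_r = 2.3 rad^2/s with run and tumble duration modulation), and a
#' propagating chemotactic wave (`scenario_wave`, direction-dependent
#' D_r of 2.3 / 3.2 / 4.4 rad^2/s for runs up / perpendicular / down the
#' propagation axis, with a ~22% tumble-duration modulation). All use
#' V_run = 20 um/s, mean run 1 s, discrete-exponential tumbles (mean 0.14 s,
#' step 0.1 s) and 10 Hz sampling.
#'
#' @param n_tracks,duration,seed Overridable sampling size parameters.
#' @return An `rt_scenario`.
#' @name reference_scenarios
NULL

#' @rdname reference_scenarios
#' @export
scenario_homogeneous <- function(n_tracks = 500, duration = 20, seed = 1L) {
  run_tumble_scenario(d_r = 2.1, n_tracks = n_tracks, duration = duration,
                      seed = seed)
}

#' @rdname reference_scenarios
#' @export
scenario_gradient <- function(n_tracks = 600, duration = 20, seed = 1L) {
  run_tumble_scenario(d_r = 2.3, gradient_axis = c(1, 0), chi_run = 0.25,
                      chi_tumble = 0.25, n_tracks = n_tracks,
                      duration = duration, seed = seed)
}

#' @rdname reference_scenarios
#' @export
scenario_wave <- function(n_tracks = 2400, duration = 20, seed = 1L) {
  run_tumble_scenario(d_r = 3.2, gradient_axis = c(1, 0), chi_run = 0.25,
                      chi_tumble = 0.13,
                      d_r_by_class = list(up = 2.3, perp = 3.2, down = 4.4),
                      n_tracks = n_tracks, duration = duration, seed = seed)
}

# classify a planar direction against the gradient axis into quadrants:
# half-open cones of half-angle `cone` about +axis (up) and -axis (down),
# the two perpendicular quadrants merged; the boundary belongs to perp
classify_direction_2d <- function(dx, dy, axis, cone_half_angle = 45) {
  ang <- angle_between_2d(dx, dy, axis[1L], axis[2L])
  cone <- cone_half_angle * pi / 180
  dplyr::case_when(
    ang < cone ~ "up",
    ang > pi - cone ~ "down",
    .default = "perp"
  )
}
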