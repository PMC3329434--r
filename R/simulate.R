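# Synthetic run-and-tumble trajectories and tumbler-mutant orientation
# series, sampled at camera frame rate, with full ground truth.

# inverse-CDF sampler for the 3D reorientation angle theta at dimensionless
# time s = D_r * tau; tables cached per rounded s. Below the series floor a
# Rayleigh small-angle draw is exact to the same order; beyond s = 5 the
# stationary density sin(theta)/2 applies.
sample_propagator_theta <- function(n, s) {
  if (n == 0L) return(numeric(0L))
  if (s <= 0) return(numeric(n))
  if (s >= 5) return(acos(1 - 2 * runif(n)))
  if (s < 2 * prop_floor()) {
    th <- sqrt(-2 * (2 * s) * log(runif(n))) # Rayleigh, sigma^2 = 2s
    return(pmin(th, pi))
  }
  key <- sprintf("cdf_%.6g", s)
  tab <- the[[key]]
  if (is.null(tab)) {
    grid <- seq(0, pi, length.out = 2048L)
    dens <- pmax(0, legendre_propagator(s, 1, grid)$density)
    cdf <- c(0, cumsum(diff(grid) * (head(dens, -1L) + tail(dens, -1L)) / 2))
    cdf <- cdf / cdf[length(cdf)]
    keep <- c(TRUE, diff(cdf) > 0)
    tab <- list(cdf = cdf[keep], grid = grid[keep])
    the[[key]] <- tab
  }
  approx(tab$cdf, tab$grid, xout = runif(n), rule = 2)$y
}

# scalar draw of one tumble duration under a (possibly modulated) mean
draw_tumble_time <- function(model, mean_scaled) {
  if (model$kind == "continuous_exponential") {
    rexp(1L, 1 / mean_scaled)
  } else {
    if (mean_scaled <= model$step) {
      abort("modulated discrete tumble mean fell at or below the step.",
            class = "rotumble_parameter_error")
    }
    model$step * (1L + rgeom(1L, model$step / mean_scaled))
  }
}

#' Simulate run-and-tumble trajectories
#'
#' Generates alternating straight runs (constant speed, exponential
#' durations) and tumbles (durations from the scenario's
#' [tumble_time_model()], reorientation by rotational diffusion), applies
#' the scenario's chemotactic modulation rules, integrates positions and
#' samples them at the camera frame rate. All phase boundaries, true
#' directions, tumble durations and reorientation angles are recorded as
#' ground truth. Deterministic given `scenario$seed`.
#'
#' @param scenario An [run_tumble_scenario()].
#' @return A list of class `rt_simulation` with elements
#'   \describe{
#'     \item{tracks}{tibble `track_id`, `t_s`, `x_um`, `y_um`, `z_um`
#'       (frame-sampled positions; `z_um` is 0 in planar mode).}
#'     \item{events}{ground-truth tibble: one row per run or tumble with
#'       `track_id`, `kind`, `t_start`, `t_end`, `duration`, run direction
#'       (`dir_x`, `dir_y`, `dir_z`), and for tumbles the true 3D angle
#'       `theta`, the observed planar turn `psi` (planar mode), the drawn
#'       duration `tau`, the preceding-run class `prev_class`, and
#'       `complete` (FALSE when cut by the end of the track).}
#'     \item{scenario}{the input scenario.}
#'   }
#' @examples
#' sim <- simulate_run_tumble(run_tumble_scenario(n_tracks = 3, duration = 5))
#' @export
simulate_run_tumble <- function(scenario) {
  stopifnot(inherits(scenario, "rt_scenario"))
  sc <- scenario
  local_seed_if(sc$seed)
  planar <- sc$mode == "planar"
  axis <- sc$gradient_axis
  frame_t <- seq(0, sc$duration, by = 1 / sc$frame_rate)

  all_tracks <- vector("list", sc$n_tracks)
  all_events <- vector("list", sc$n_tracks)

  for (tr in seq_len(sc$n_tracks)) {
    # generous phase-capacity guess, grown on demand
    cap <- max(16L, ceiling(2.5 * sc$duration /
                              (sc$mean_run * (1 - sc$chi_run) + 1e-9)) + 8L)
    ev_kind <- character(cap); ev_t0 <- ev_t1 <- ev_dur <- numeric(cap)
    ev_dx <- ev_dy <- ev_dz <- ev_theta <- ev_psi <- ev_tau <- numeric(cap)
    ev_class <- character(cap); ev_complete <- logical(cap)
    ne <- 0L

    if (planar) {
      ang <- runif(1L, 0, 2 * pi)
      dir <- c(cos(ang), sin(ang), 0)
    } else {
      dir <- as.numeric(runif_sphere(1L))
    }
    pos <- c(0, 0, 0)
    knot_t <- numeric(2L * cap + 1L)
    knot_xyz <- matrix(0, 2L * cap + 1L, 3L)
    nk <- 1L
    t_now <- 0

    grow <- function() {
      ev_kind <<- c(ev_kind, character(cap)); ev_t0 <<- c(ev_t0, numeric(cap))
      ev_t1 <<- c(ev_t1, numeric(cap)); ev_dur <<- c(ev_dur, numeric(cap))
      ev_dx <<- c(ev_dx, numeric(cap)); ev_dy <<- c(ev_dy, numeric(cap))
      ev_dz <<- c(ev_dz, numeric(cap)); ev_theta <<- c(ev_theta, numeric(cap))
      ev_psi <<- c(ev_psi, numeric(cap)); ev_tau <<- c(ev_tau, numeric(cap))
      ev_class <<- c(ev_class, character(cap))
      ev_complete <<- c(ev_complete, logical(cap))
      knot_t <<- c(knot_t, numeric(2L * cap))
      knot_xyz <<- rbind(knot_xyz, matrix(0, 2L * cap, 3L))
      cap <<- 2L * cap
    }

    while (t_now < sc$duration) {
      cg <- if (is.null(axis)) 0 else sum(dir[1:2] * axis)
      # ---- run ----
      run_mean <- sc$mean_run * (1 + sc$chi_run * cg)
      dur <- rexp(1L, 1 / run_mean)
      t_end <- t_now + dur
      complete <- t_end <= sc$duration
      if (!complete) { t_end <- sc$duration; dur <- t_end - t_now }
      pos <- pos + sc$v_run * dur * dir
      if (ne + 2L > cap || nk + 2L > length(knot_t)) grow()
      ne <- ne + 1L
      ev_kind[ne] <- "run"; ev_t0[ne] <- t_now; ev_t1[ne] <- t_end
      ev_dur[ne] <- dur; ev_dx[ne] <- dir[1L]; ev_dy[ne] <- dir[2L]
      ev_dz[ne] <- dir[3L]; ev_theta[ne] <- NA_real_; ev_psi[ne] <- NA_real_
      ev_tau[ne] <- NA_real_; ev_class[ne] <- NA_character_
      ev_complete[ne] <- complete
      nk <- nk + 1L; knot_t[nk] <- t_end; knot_xyz[nk, ] <- pos
      t_now <- t_end
      if (!complete || t_now >= sc$duration) break
      # ---- tumble ----
      prev_class <- if (is.null(axis)) "none" else
        classify_direction_2d(dir[1L], dir[2L], axis)
      tum_mean <- sc$tumble_model$mean * (1 - sc$chi_tumble * cg)
      tau <- draw_tumble_time(sc$tumble_model, tum_mean)
      d_ev <- if (!is.null(sc$d_r_by_class) && prev_class != "none") {
        sc$d_r_by_class[[prev_class]]
      } else {
        sc$d_r
      }
      theta <- sample_propagator_theta(1L, d_ev * tau)
      t_end <- t_now + tau
      complete <- t_end <= sc$duration
      if (!complete) t_end <- sc$duration
      if (planar) {
        psi <- wrap_angle(rnorm(1L, 0, sqrt(2 * d_ev * tau)))
        ca <- cos(psi); sa <- sin(psi)
        dir <- c(ca * dir[1L] - sa * dir[2L], sa * dir[1L] + ca * dir[2L], 0)
      } else {
        psi <- NA_real_
        beta <- runif(1L, 0, 2 * pi)
        nd <- c(sin(theta) * cos(beta), sin(theta) * sin(beta), cos(theta))
        dir <- as.numeric(rotate_z_onto(matrix(nd, 1L, 3L), dir))
      }
      ne <- ne + 1L
      ev_kind[ne] <- "tumble"; ev_t0[ne] <- t_now; ev_t1[ne] <- t_end
      ev_dur[ne] <- t_end - ev_t0[ne]; ev_dx[ne] <- NA_real_
      ev_dy[ne] <- NA_real_; ev_dz[ne] <- NA_real_
      ev_theta[ne] <- theta; ev_psi[ne] <- psi; ev_tau[ne] <- tau
      ev_class[ne] <- prev_class; ev_complete[ne] <- complete
      nk <- nk + 1L; knot_t[nk] <- t_end; knot_xyz[nk, ] <- pos
      t_now <- t_end
    }

    xs <- approx(knot_t[1:nk], knot_xyz[1:nk, 1L], xout = frame_t, rule = 2)$y
    ys <- approx(knot_t[1:nk], knot_xyz[1:nk, 2L], xout = frame_t, rule = 2)$y
    zs <- approx(knot_t[1:nk], knot_xyz[1:nk, 3L], xout = frame_t, rule = 2)$y
    all_tracks[[tr]] <- tibble::tibble(
      track_id = tr, t_s = frame_t, x_um = xs, y_um = ys, z_um = zs
    )
    idx <- seq_len(ne)
    all_events[[tr]] <- tibble::tibble(
      track_id = tr, kind = ev_kind[idx], t_start = ev_t0[idx],
      t_end = ev_t1[idx], duration = ev_dur[idx], dir_x = ev_dx[idx],
      dir_y = ev_dy[idx], dir_z = ev_dz[idx], theta = ev_theta[idx],
      psi = ev_psi[idx], tau = ev_tau[idx], prev_class = ev_class[idx],
      complete = ev_complete[idx]
    )
  }

  out <- list(tracks = dplyr::bind_rows(all_tracks),
              events = dplyr::bind_rows(all_events),
              scenario = sc)
  class(out) <- "rt_simulation"
  out
}

#' @export
print.rt_simulation <- function(x, ...) {
  cat(sprintf("<rt_simulation> %d tracks, %d frames, %d ground-truth events\n",
              x$scenario$n_tracks, nrow(x$tracks),
              sum(x$events$kind == "tumble")))
  invisible(x)
}

#' Ground-truth tumble events of a simulation
#'
#' Complete tumble events flanked by complete runs, in the column layout of
#' [reorientation_events()] (`psi` folded to \eqn{[0, \pi]}), for oracle
#' comparisons against the analysis pipeline.
#'
#' @param sim An `rt_simulation`.
#' @return Tibble with `track_id`, `t_start`, `psi`, `theta`, `tau`,
#'   `prev_class`.
#' @export
true_events <- function(sim) {
  stopifnot(inherits(sim, "rt_simulation"))
  ev <- sim$events
  dplyr::filter(ev, .data$kind == "tumble", .data$complete,
                !is.na(.data$tau)) |>
    dplyr::transmute(
      track_id = .data$track_id, t_start = .data$t_start,
      psi = abs(wrap_angle(.data$psi)), theta = .data$theta, tau = .data$tau,
      prev_class = .data$prev_class
    )
}

#' Project a simulated trajectory onto the observation plane
#'
#' Orthogonal projection of the frame-sampled positions onto the plane with
#' unit normal `plane_normal`; ground-truth tumble events retain the 3D
#' reorientation angle `theta` alongside the projected planar angle `psi`
#' (for `"3d"`-mode simulations `psi` is recomputed as the angle between the
#' projected directions of the flanking runs).
#'
#' @param sim An `rt_simulation`.
#' @param plane_normal Unit 3-vector normal of the observation plane
#'   (default the optical axis `+z`).
#' @return A list of class `rt_projection` with `tracks` (tibble `track_id`,
#'   `t_s`, `x_um`, `y_um` in plane coordinates), `events` (as
#'   [true_events()], `psi` projected) and `plane_normal`.
#' @export
project_to_plane <- function(sim, plane_normal = c(0, 0, 1)) {
  stopifnot(inherits(sim, "rt_simulation"))
  nrm <- sqrt(sum(plane_normal^2))
  if (abs(nrm - 1) > 1e-6) {
    abort("`plane_normal` must be a unit vector.",
          class = "rotumble_domain_error")
  }
  plane_normal <- plane_normal / nrm
  # in-plane orthonormal basis
  ref <- if (abs(plane_normal[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * plane_normal) * plane_normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(plane_normal[2L] * e1[3L] - plane_normal[3L] * e1[2L],
          plane_normal[3L] * e1[1L] - plane_normal[1L] * e1[3L],
          plane_normal[1L] * e1[2L] - plane_normal[2L] * e1[1L])
  if (abs(plane_normal[3L] - 1) < 1e-12) { # keep lab x/y for the optical axis
    e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  }
  P <- cbind(e1, e2)
  xy <- as.matrix(sim$tracks[, c("x_um", "y_um", "z_um")]) %*% P
  tracks <- tibble::tibble(track_id = sim$tracks$track_id,
                           t_s = sim$tracks$t_s,
                           x_um = xy[, 1L], y_um = xy[, 2L])

  if (sim$scenario$mode == "planar") {
    events <- true_events(sim)
  } else {
    ev <- sim$events
    # angle between projected directions of the flanking runs
    runs <- which(ev$kind == "run")
    tums <- which(ev$kind == "tumble" & ev$complete)
    u <- as.matrix(ev[, c("dir_x", "dir_y", "dir_z")]) %*% P
    psi_proj <- rep(NA_real_, nrow(ev))
    for (i in tums) {
      if (i > 1L && i < nrow(ev) &&
          ev$kind[i - 1L] == "run" && ev$kind[i + 1L] == "run" &&
          ev$track_id[i - 1L] == ev$track_id[i + 1L]) {
        a <- u[i - 1L, ]; b <- u[i + 1L, ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na > 1e-12 && nb > 1e-12) {
          psi_proj[i] <- angle_between_2d(a[1L], a[2L], b[1L], b[2L])
        }
      }
    }
    events <- ev |>
      dplyr::mutate(psi = psi_proj) |>
      dplyr::filter(.data$kind == "tumble", .data$complete,
                    !is.na(.data$psi)) |>
      dplyr::transmute(track_id = .data$track_id, t_start = .data$t_start,
                       psi = .data$psi, theta = .data$theta, tau = .data$tau,
                       prev_class = .data$prev_class)
  }
  structure(list(tracks = tracks, events = events,
                 plane_normal = plane_normal),
            class = "rt_projection")
}

#' Simulate tumbler-mutant orientation series
#'
#' CheZ-deleted "tumbler" mutants reorient continuously without swimming;
#' high-magnification tracking reports the planar angle \eqn{\psi} of the
#' projected body axis at each frame. Under the near-plane observation model
#' the frame-to-frame increments of \eqn{\psi} are Gaussian with variance
#' \eqn{2 D_r \Delta t}, so
#' \eqn{\langle\cos(\psi(t+\tau) - \psi(t))\rangle = \exp(-D_r \tau)}.
#'
#' @param d_r Rotational diffusion coefficient, rad^2/s.
#' @param frame_rate Frames per second (default 50).
#' @param duration Series duration per cell, s.
#' @param n_cells Number of cells.
#' @param seed Optional integer seed.
#' @return Tibble with columns `cell_id`, `t_s`, `psi_rad` (unwrapped,
#'   continuous).
#' @examples
#' simulate_tumbler(2.4, duration = 2, n_cells = 2, seed = 1)
#' @export
simulate_tumbler <- function(d_r, frame_rate = 50, duration = 20,
                             n_cells = 20, seed = NULL) {
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  check_positive_scalar(frame_rate, "frame_rate")
  check_positive_scalar(duration, "duration")
  if (frame_rate < 10 * d_r / (2 * pi)) {
    warn(sprintf(
      "frame_rate %g Hz may alias the decorrelation at d_r = %g rad^2/s.",
      frame_rate, d_r))
  }
  local_seed_if(seed)
  dt <- 1 / frame_rate
  n_frames <- floor(duration * frame_rate) + 1L
  purrr::map_dfr(seq_len(n_cells), function(cell) {
    psi0 <- runif(1L, 0, 2 * pi)
    inc <- rnorm(n_frames - 1L, 0, sqrt(2 * d_r * dt))
    tibble::tibble(cell_id = cell, t_s = (seq_len(n_frames) - 1L) * dt,
                   psi_rad = psi0 + c(0, cumsum(inc)))
  })
}
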