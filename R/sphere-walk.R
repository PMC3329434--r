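# Monte-Carlo random walk of a unit vector on the sphere: the brute-force
# oracle for the Legendre propagator and the reorientation engine for
# tumbles. Each step applies independent Gaussian angular increments of
# variance 2 D_r dt about two orthonormal tangent axes and renormalizes; the
# per-step angular variance 4 D_r dt is capped at 0.1 rad^2 by internal
# sub-stepping so the tangent-plane approximation stays accurate.

STEP_VAR_CAP <- 0.1

# advance an n x 3 matrix of unit vectors by one tangent-plane Gaussian step
# with per-axis standard deviation sdv (vector or scalar)
sphere_step <- function(n3, sdv) {
  nx <- n3[, 1L]; ny <- n3[, 2L]; nz <- n3[, 3L]
  # tangent axis 1: normalize(z x n) (azimuthal); fall back at the poles
  hx <- -ny; hy <- nx
  hn <- sqrt(hx^2 + hy^2)
  bad <- hn < 1e-12
  hx[bad] <- 1; hy[bad] <- 0; hn[bad] <- 1
  hx <- hx / hn; hy <- hy / hn
  # tangent axis 2: n x h
  e2x <- -nz * hy
  e2y <- nz * hx
  e2z <- nx * hy - ny * hx
  g1 <- rnorm(nrow(n3), 0, sdv)
  g2 <- rnorm(nrow(n3), 0, sdv)
  # rotate exactly through the Gaussian angle |g| about the tangent
  # direction g/|g| (plain displacement + renormalization shortens steps
  # and biases <cos theta> upward by O(dt) )
  g <- sqrt(g1^2 + g2^2)
  g[g < 1e-300] <- 1e-300
  cg <- cos(g)
  sg <- sin(g) / g
  out <- cbind(cg * nx + sg * (g1 * hx + g2 * e2x),
               cg * ny + sg * (g1 * hy + g2 * e2y),
               cg * nz + sg * (g2 * e2z))
  out / sqrt(rowSums(out^2))
}

#' Simulate a rotational Brownian walk on the unit sphere
#'
#' The extremity of a unit vector performing rotational diffusion with
#' coefficient `d_r` describes a random walk on the sphere. Steps of duration
#' `dt` are recorded; when the per-step angular variance \eqn{4 D_r dt}
#' exceeds 0.1 rad\eqn{^2} each step is subdivided internally so the
#' tangent-plane Gaussian increments remain a faithful discretization.
#'
#' @param d_r Rotational diffusion coefficient, rad^2/s (\eqn{\ge 0}).
#' @param dt Recording time step, s.
#' @param n_steps Number of recorded steps.
#' @param seed Optional integer seed; the walk is deterministic given it.
#' @param start Unit 3-vector starting orientation (default `+z`).
#' @return A tibble of class `sphere_walk` with columns `step`, `t`, `x`,
#'   `y`, `z` (`n_steps + 1` rows including the start).
#' @examples
#' w <- simulate_sphere_walk(0.16, dt = 0.03, n_steps = 100, seed = 1)
#' @export
simulate_sphere_walk <- function(d_r, dt, n_steps, seed = NULL,
                                 start = c(0, 0, 1)) {
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  check_positive_scalar(dt, "dt")
  if (!is.numeric(n_steps) || n_steps < 1) {
    abort("`n_steps` must be >= 1.", class = "rotumble_parameter_error")
  }
  nrm <- sqrt(sum(start^2))
  if (abs(nrm - 1) > 1e-6) {
    abort("`start` must be a unit vector.", class = "rotumble_domain_error")
  }
  start <- start / nrm
  local_seed_if(seed)
  n_steps <- as.integer(n_steps)
  m <- max(1L, ceiling(4 * d_r * dt / STEP_VAR_CAP))
  sdv <- sqrt(2 * d_r * dt / m)
  pos <- matrix(start, 1L, 3L)
  out <- matrix(0, n_steps + 1L, 3L)
  out[1L, ] <- start
  for (k in seq_len(n_steps)) {
    if (d_r > 0) for (j in seq_len(m)) pos <- sphere_step(pos, sdv)
    out[k + 1L, ] <- pos
  }
  res <- tibble::tibble(
    step = 0:n_steps, t = (0:n_steps) * dt,
    x = out[, 1L], y = out[, 2L], z = out[, 3L]
  )
  class(res) <- c("sphere_walk", class(res))
  attr(res, "d_r") <- d_r
  attr(res, "dt") <- dt
  res
}

# vectorized endpoint sampler: final unit vectors (from +z) after diffusing
# for durations[i] at coefficient d_r; sub-step counts chosen per element
sphere_walk_endpoints <- function(d_r, durations) {
  n <- length(durations)
  out <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  if (d_r == 0 || n == 0L) return(out)
  m <- pmax(1L, ceiling(4 * d_r * durations / STEP_VAR_CAP))
  sdv_full <- sqrt(2 * d_r * durations / m)
  mx <- max(m)
  active <- durations > 0
  for (k in seq_len(mx)) {
    idx <- which(active & m >= k)
    if (length(idx) == 0L) break
    out[idx, ] <- sphere_step(out[idx, , drop = FALSE], sdv_full[idx])
  }
  out
}

#' Sample tumble reorientations by rotational diffusion
#'
#' Draws the 3D reorientation produced by a tumble of given duration: the
#' orientation diffuses on the sphere for `tumble_duration` seconds at
#' coefficient `d_r`. Over repeated calls the polar angle `theta` between the
#' incoming and outgoing directions follows [legendre_propagator()] at the
#' same time.
#'
#' @inheritParams simulate_sphere_walk
#' @param tumble_duration Tumble duration(s), s; vectorized.
#' @param start Incoming direction (unit 3-vector).
#' @return A tibble with columns `theta` (rad, in \eqn{[0, \pi]}) and the
#'   outgoing direction `x`, `y`, `z`, one row per duration.
#' @examples
#' sample_reorientation(3.5, rep(0.14, 5), seed = 1)
#' @export
sample_reorientation <- function(d_r, tumble_duration, seed = NULL,
                                 start = c(0, 0, 1)) {
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  check_time_nonneg(tumble_duration)
  local_seed_if(seed)
  ends <- sphere_walk_endpoints(d_r, tumble_duration)
  theta <- acos(pmin(1, pmax(-1, ends[, 3L])))
  nrm <- sqrt(sum(start^2))
  start <- start / nrm
  ends <- rotate_z_onto(ends, start)
  tibble::tibble(theta = theta, x = ends[, 1L], y = ends[, 2L], z = ends[, 3L])
}

#' @method autoplot sphere_walk
#' @export
autoplot.sphere_walk <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$t)) +
    ggplot2::geom_path(...) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Rotational Brownian walk (xy projection)",
                  x = "n_x", y = "n_y", colour = "t (s)")
}
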