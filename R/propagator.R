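# Rotational-diffusion propagator on the sphere and directional correlations.
#
# Starting from a delta-function orientation p(theta, 0) = delta(theta), the
# polar-angle density after diffusing for time t with coefficient D_r is
#
#   p(theta, t) = sin(theta) * sum_l (l + 1/2) exp(-l (l + 1) D_r t) P_l(cos theta)
#
# i.e. the spherical-harmonic expansion of the orientational Green's function
# multiplied by the sin(theta) measure, so that p integrates to 1 over
# [0, pi]. The series is truncated adaptively once the mode weight
# exp(-l (l + 1) D_r t) drops below 1e-12, with a hard cap at l = 500.

PROP_LOG_TOL <- -log(1e-12) # 27.63
PROP_L_CAP <- 500L

# minimal truncation order so that exp(-l(l+1) s) < 1e-12
prop_order <- function(s) {
  max(1, ceiling((-1 + sqrt(1 + 4 * PROP_LOG_TOL / s)) / 2))
}

# dimensionless time below which the capped series has not converged
prop_floor <- function() PROP_LOG_TOL / (PROP_L_CAP * (PROP_L_CAP + 1L))

new_orientation_density <- function(theta, density, time_tag, d_r) {
  out <- tibble::tibble(theta = theta, density = density)
  class(out) <- c("orientation_density", class(out))
  attr(out, "time_tag") <- time_tag
  attr(out, "d_r") <- d_r
  out
}

#' Orientation propagator of rotational diffusion
#'
#' Probability density of the polar reorientation angle \eqn{\theta} after a
#' particle whose orientation undergoes rotational diffusion with coefficient
#' `d_r` (rad\eqn{^2}/s) has diffused for time `t`, starting aligned with the
#' polar axis. The density is returned per unit \eqn{\theta} (it already
#' contains the \eqn{\sin\theta} surface measure), so its trapezoid integral
#' over \eqn{[0, \pi]} is 1. As \eqn{D_r t \to \infty} it converges to the
#' isotropic density \eqn{\sin(\theta)/2}.
#'
#' @param t Diffusion time in seconds (scalar, \eqn{\ge 0}).
#' @param d_r Rotational diffusion coefficient, rad\eqn{^2}/s.
#' @param theta_grid Grid of polar angles covering \eqn{[0, \pi]} (radians).
#' @param l_max Truncation order of the Legendre series, or `"auto"` to pick
#'   the smallest order whose mode weight falls below 1e-12 (capped at 500).
#'
#' @details At `t = 0` the delta-function initial condition is represented by
#'   a documented discrete convention: all probability mass is assigned to the
#'   first grid cell (trapezoid weight), so the integral remains 1. For
#'   \eqn{D_r t} below roughly 1.1e-4 the capped series has not converged and
#'   an error asks for the delta convention or the Monte-Carlo sampler
#'   ([simulate_sphere_walk()]) instead.
#'
#' @return A tibble of class `orientation_density` with columns `theta` and
#'   `density`, and attributes `time_tag` and `d_r`.
#' @examples
#' pd <- legendre_propagator(0.2, d_r = 1)
#' sum(diff(pd$theta) * (head(pd$density, -1) + tail(pd$density, -1)) / 2)
#' @seealso [direction_autocorrelation()], [reorientation_distribution()]
#' @export
legendre_propagator <- function(t, d_r, theta_grid = NULL, l_max = "auto") {
  check_time_nonneg(t)
  if (length(t) != 1L) {
    abort("`t` must be a single time.", class = "rotumble_domain_error")
  }
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  if (is.null(theta_grid)) theta_grid <- seq(0, pi, length.out = 1024L)
  if (min(theta_grid) > 1e-12 || max(theta_grid) < pi - 1e-12) {
    abort("`theta_grid` must cover [0, pi].", class = "rotumble_domain_error")
  }
  if (t == 0 || d_r == 0) {
    density <- numeric(length(theta_grid))
    # trapezoid mass of the first node is (theta_2 - theta_1)/2
    density[1L] <- 2 / (theta_grid[2L] - theta_grid[1L])
    return(new_orientation_density(theta_grid, density, time_tag = t, d_r = d_r))
  }
  s <- d_r * t
  if (identical(l_max, "auto")) {
    L <- prop_order(s)
    if (L > PROP_L_CAP) {
      abort(
        sprintf(paste0(
          "Legendre series not converged at l = %d (D_r * t = %.3g is below ",
          "the floor %.3g); use the t = 0 delta convention or the Monte-Carlo ",
          "sampler simulate_sphere_walk()."), PROP_L_CAP, s, prop_floor()),
        class = "rotumble_numeric_error"
      )
    }
  } else {
    L <- min(as.integer(l_max), PROP_L_CAP)
  }
  l <- 0:L
  w <- (l + 0.5) * exp(-l * (l + 1) * s)
  density <- sin(theta_grid) * legendre_series(cos(theta_grid), w)
  new_orientation_density(theta_grid, density, time_tag = t, d_r = d_r)
}

#' Directional autocorrelation of rotational diffusion in 3D
#'
#' Mean cosine of the 3D reorientation angle after time `t`,
#' \eqn{\langle\cos\theta\rangle(t) = \exp(-2 D_r t)}: the first Legendre
#' moment of the orientation propagator.
#'
#' @inheritParams legendre_propagator
#' @param t Time(s) in seconds; vectorized.
#' @return A tibble with columns `lag` and `value`.
#' @export
direction_autocorrelation <- function(t, d_r) {
  check_time_nonneg(t)
  check_positive_scalar(d_r, "d_r", allow_zero = TRUE)
  tibble::tibble(lag = t, value = exp(-2 * d_r * t))
}

# exact probability that theta falls in [breaks_i, breaks_{i+1}] under the
# propagator at dimensionless time s, using the Legendre antiderivative
#   int P_l(x) dx = (P_{l+1}(x) - P_{l-1}(x)) / (2 l + 1)
propagator_bin_probs <- function(s, breaks) {
  L <- prop_order(s)
  if (L > PROP_L_CAP) {
    abort(sprintf("D_r * t = %.3g below series floor %.3g.", s, prop_floor()),
          class = "rotumble_numeric_error")
  }
  x <- cos(breaks) # decreasing in theta
  P <- legendre_matrix(x, L + 1L)
  l <- 0:L
  w <- exp(-l * (l + 1) * s) / 2 # (l + 1/2) / (2 l + 1) = 1/2
  # antiderivative G_l(x): l = 0 -> x, else (P_{l+1} - P_{l-1})/(2l+1) * (2l+1)
  # note: with weight (l+1/2)/(2l+1) the (2l+1) cancels
  G <- matrix(0, length(x), L + 1L)
  G[, 1L] <- x
  if (L >= 1L) for (ll in 1:L) G[, ll + 1L] <- P[, ll + 2L] - P[, ll]
  # prob over [theta_i, theta_{i+1}] = sum_l w_l (G_l(x_i) - G_l(x_{i+1}))
  vals <- G %*% w
  as.numeric(head(vals, -1L) - tail(vals, -1L))
}

#' Stokes-Einstein-Debye rotational diffusion coefficient
#'
#' Thermal rotational diffusion coefficient of a sphere of radius `radius` in
#' a fluid of dynamic viscosity `viscosity` at temperature `temperature`:
#' \eqn{D_r = k_B T / (8 \pi \eta a^3)}, in rad\eqn{^2}/s. For a 1 um sphere
#' in water-like viscosity (1 mPa s) at 295 K this gives 0.16 rad\eqn{^2}/s,
#' two orders of magnitude below the active coefficients measured for
#' tumbling bacteria.
#'
#' @param radius Hydrodynamic radius, m.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param temperature Absolute temperature, K.
#' @return Rotational diffusion coefficient, rad^2/s.
#' @examples
#' stokes_einstein_rotational(1e-6, 1e-3, 295)
#' @export
stokes_einstein_rotational <- function(radius, viscosity, temperature) {
  check_positive_scalar(radius, "radius")
  check_positive_scalar(viscosity, "viscosity")
  check_positive_scalar(temperature, "temperature")
  kB <- 1.380649e-23
  kB * temperature / (8 * pi * viscosity * radius^3)
}

#' @export
print.orientation_density <- function(x, ...) {
  cat(sprintf("<orientation_density> %d grid points, time tag: %s\n",
              nrow(x), format(attr(x, "time_tag"))))
  NextMethod()
}

#' @method autoplot orientation_density
#' @export
autoplot.orientation_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$density)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(
      x = expression(theta ~ "(rad)"),
      y = expression(p(theta)),
      title = sprintf("Reorientation density (time tag: %s)",
                      format(attr(object, "time_tag")))
    )
}
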