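# internal helpers: angle arithmetic, validation, seeded evaluation

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# smallest unsigned angle between two planar directions, in [0, pi]
angle_between_2d <- function(ax, ay, bx, by) {
  abs(wrap_angle(atan2(by, bx) - atan2(ay, ax)))
}

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer.", class = "rotumble_parameter_error")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    abort(
      sprintf("`%s` must be a %s number.", name,
              if (allow_zero) "single non-negative" else "single positive"),
      class = "rotumble_domain_error"
    )
  }
  invisible(x)
}

check_time_nonneg <- function(t) {
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    abort("times must be non-negative.", class = "rotumble_domain_error")
  }
  invisible(t)
}

# evaluate sum_l w[l+1] * P_l(x) by the three-term Legendre recurrence,
# vectorized over x
legendre_series <- function(x, w) {
  L <- length(w) - 1L
  p_prev <- rep(1, length(x))
  acc <- w[1L] * p_prev
  if (L >= 1L) {
    p_cur <- x
    acc <- acc + w[2L] * p_cur
  }
  if (L >= 2L) {
    for (l in 2:L) {
      p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
      acc <- acc + w[l + 1L] * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc
}

# matrix of P_l(x) for l = 0..lmax (columns), x a vector (rows)
legendre_matrix <- function(x, lmax) {
  P <- matrix(0, length(x), lmax + 1L)
  P[, 1L] <- 1
  if (lmax >= 1L) P[, 2L] <- x
  if (lmax >= 2L) {
    for (l in 2:lmax) {
      P[, l + 1L] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1L]) / l
    }
  }
  P
}

trapz_int <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

# unit 3D vector drawn uniformly on the sphere, n x 3 matrix
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Rodrigues rotation taking +z onto `to` (unit 3-vector), applied to rows of m
rotate_z_onto <- function(m, to) {
  tz <- to[3L]
  if (abs(tz - 1) < 1e-12) return(m)
  if (abs(tz + 1) < 1e-12) return(cbind(m[, 1L], -m[, 2L], -m[, 3L]))
  # axis = z x to (normalized), angle = acos(tz)
  ax <- c(-to[2L], to[1L], 0)
  ax <- ax / sqrt(sum(ax^2))
  ct <- tz
  st <- sqrt(max(0, 1 - tz^2))
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L], -ax[2L], ax[1L], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3L) + st * K + (1 - ct) * (K %*% K)
  m %*% t(R)
}
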