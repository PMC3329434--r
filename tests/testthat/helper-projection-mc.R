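# Monte-Carlo oracle for the isotropic 3D -> 2D pair projection: for each
# 3D separation angle theta[i], orient the pair uniformly at random relative
# to the z = 0 plane, project both directions, and return cos of the planar
# angle between the projections.
mc_pair_projection_cos <- function(theta) {
  n <- length(theta)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  u <- cbind(r * cos(phi), r * sin(phi), z)
  h <- cbind(-u[, 2], u[, 1], 0)
  hn <- sqrt(h[, 1]^2 + h[, 2]^2)
  bad <- which(hn < 1e-9)
  if (length(bad) > 0) {
    h[bad, ] <- matrix(c(1, 0, 0), length(bad), 3, byrow = TRUE)
    hn[bad] <- 1
  }
  h <- h / hn
  e2 <- cbind(u[, 2] * h[, 3] - u[, 3] * h[, 2],
              u[, 3] * h[, 1] - u[, 1] * h[, 3],
              u[, 1] * h[, 2] - u[, 2] * h[, 1])
  b <- runif(n, 0, 2 * pi)
  v <- cos(theta) * u + sin(theta) * (cos(b) * h + sin(b) * e2)
  (u[, 1] * v[, 1] + u[, 2] * v[, 2]) /
    (sqrt(u[, 1]^2 + u[, 2]^2) * sqrt(v[, 1]^2 + v[, 2]^2))
}
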