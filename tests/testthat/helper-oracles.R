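# shared test utilities and independent oracles

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# chi-square goodness of fit of angle samples against an expected density
# given on a grid; bins pooled so every expected count is >= 5
chisq_gof_angles <- function(angles, grid, density, n_bins = 30) {
  breaks <- seq(0, pi, length.out = n_bins + 1)
  cdf <- c(0, cumsum(diff(grid) * (head(density, -1) + tail(density, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  p <- diff(approx(grid, cdf, xout = breaks, rule = 2)$y)
  obs <- tabulate(findInterval(angles, breaks, all.inside = TRUE), n_bins)
  expct <- sum(obs) * p / sum(p)
  keep <- expct >= 5
  # pool the sparse tail into the last kept bin
  if (any(!keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    expct <- c(expct[keep], sum(expct[!keep]))
  }
  stat <- sum((obs - expct)^2 / expct)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

# two-sided z-style check: |x - mu| <= k standard errors
within_se <- function(x, mu, se, k = 3) abs(x - mu) <= k * se

# draw n reorientation angles from the tumble-time-marginalized propagator
# (tau from the duration model, then theta | tau), grouped by duration for
# speed; uses the current RNG state
draw_marginal_angles <- function(n, d_r, model) {
  tau <- sample_tumble_times(model, n)
  th <- numeric(n)
  for (u in unique(tau)) {
    idx <- which(tau == u)
    th[idx] <- rotumble:::sample_propagator_theta(length(idx), d_r * u)
  }
  th
}
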