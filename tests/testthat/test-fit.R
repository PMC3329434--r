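# D_r estimators on correlation curves

noiseless_curve <- function(tau, value) {
  out <- tibble::tibble(tau = tau, mean_cos = value, n = 1000L,
                        se = rep(1e-3, length(tau)))
  class(out) <- c("rt_curve", class(out))
  attr(out, "bin_width") <- diff(tau)[1]
  attr(out, "min_count") <- 10L
  out
}

test_that("noiseless self-fits are exact for both methods", {
  tau <- seq(0.1, 0.6, by = 0.1)
  cv <- noiseless_curve(tau, exp(-2.1 * tau))
  f <- fit_exponential(cv, "projected", n_boot = 0)
  expect_equal(f$d_r_hat, 2.1, tolerance = 1e-6)
  # full3d convention: <cos theta> = exp(-2 d_r tau)
  cv3 <- noiseless_curve(tau, exp(-2 * 1.7 * tau))
  f3 <- fit_exponential(cv3, "full3d", n_boot = 0)
  expect_equal(f3$d_r_hat, 1.7, tolerance = 1e-6)
  # exact projection family, planar and isotropic3d references
  cvp <- noiseless_curve(tau, projected_autocorrelation(tau, 3)$value)
  expect_equal(fit_exact_projection(cvp, n_boot = 0)$d_r_hat, 3,
               tolerance = 1e-4)
  cvi <- noiseless_curve(tau,
                         projected_autocorrelation(tau, 3, "isotropic3d")$value)
  expect_equal(fit_exact_projection(cvi, "isotropic3d", n_boot = 0)$d_r_hat,
               3, tolerance = 1e-4)
})

test_that("degenerate and underdetermined curves are refused or flagged", {
  tau <- seq(0.1, 0.5, by = 0.1)
  flat <- noiseless_curve(tau, rep(1, 5))
  f <- fit_exponential(flat, n_boot = 0)
  expect_true(f$flagged)
  expect_error(fit_exponential(noiseless_curve(c(0.1, 0.2), exp(-c(0.1, 0.2)))),
               class = "rotumble_parameter_error")
  # long-tumble (fully randomized) data carry almost no rate information:
  # with realistic bin SEs the rate uncertainty blows up
  iso <- noiseless_curve(seq(1.6, 2.0, 0.1), rep(0.001, 5))
  iso$se <- rep(0.03, 5) # cos of near-uniform angles, ~1000 events per bin
  fi <- fit_exact_projection(iso, n_boot = 0)
  expect_true(fi$flagged || fi$stderr > 1)
})

test_that("rescaling time rescales the fitted rate inversely", {
  tau <- seq(0.1, 0.6, by = 0.1)
  cv <- noiseless_curve(tau, exp(-1.3 * tau))
  cv2 <- noiseless_curve(2 * tau, exp(-1.3 * tau))
  f1 <- fit_exponential(cv, n_boot = 0)
  f2 <- fit_exponential(cv2, n_boot = 0)
  expect_equal(f1$d_r_hat, 2 * f2$d_r_hat, tolerance = 1e-5)
})

test_that("tidy and glance expose the fit in broom layout", {
  cv <- noiseless_curve(seq(0.1, 0.6, 0.1), exp(-2.1 * seq(0.1, 0.6, 0.1)))
  f <- fit_exponential(cv, n_boot = 0)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "method"))
  expect_equal(td$estimate, f$d_r_hat)
  gl <- glance(f)
  expect_true(all(c("d_r_hat", "objective", "converged", "flagged") %in%
                    names(gl)))
})

test_that("exponential and exact-projection fits agree on simulated data", {
  md <- tumble_time_model("discrete_exponential", 0.14, 0.1)
  withr::with_seed(61, {
    tau <- sample_tumble_times(md, 8000)
    psi <- abs(rnorm(8000, 0, sqrt(2 * 2.1 * tau)))
  })
  ev <- tibble::tibble(psi = psi, tau = tau)
  cv <- correlation_curve(ev)
  fe <- fit_exponential(cv, n_boot = 0)
  fx <- fit_exact_projection(cv, n_boot = 0)
  expect_lte(abs(fe$d_r_hat - fx$d_r_hat) / fx$d_r_hat, 0.10)
  expect_equal(fe$d_r_hat, 2.1, tolerance = 0.2)
})

test_that("one-SE interval covers the truth at the expected rate", {
  # 100 stochastic replicates at tracking-experiment scale: the +-1 SE
  # (event bootstrap) interval should cover the generating value in
  # 60-80% of replicates
  md <- tumble_time_model("discrete_exponential", 0.14, 0.1)
  withr::with_seed(62, {
    cover <- vapply(1:100, function(b) {
      tau <- sample_tumble_times(md, 3000)
      psi <- abs(rnorm(3000, 0, sqrt(2 * 2.1 * tau)))
      ev <- tibble::tibble(psi = psi, tau = tau)
      cv <- correlation_curve(ev)
      f <- fit_exponential(cv, events = ev, n_boot = 120)
      abs(f$d_r_hat - 2.1) <= f$stderr
    }, logical(1))
  })
  expect_gte(mean(cover), 0.60)
  expect_lte(mean(cover), 0.80)
})

test_that("per-class fits separate direction-dependent coefficients", {
  md <- tumble_time_model("discrete_exponential", 0.14, 0.1)
  gen <- c(up = 2.3, perp = 3.2, down = 4.4)
  withr::with_seed(63, {
    ev <- purrr::map_dfr(names(gen), function(cl) {
      n <- if (cl == "perp") 8000L else 4000L
      tau <- sample_tumble_times(md, n)
      tibble::tibble(psi = abs(rnorm(n, 0, sqrt(2 * gen[[cl]] * tau))),
                     tau = tau, prev_class = cl)
    })
  })
  fits <- fit_by_class(ev, n_boot = 80, seed = 64)
  for (cl in names(gen)) {
    expect_equal(fits$d_r_hat[fits$class == cl], gen[[cl]], tolerance = 0.4)
  }
  expect_false(attr(fits, "homogeneous"))
  # single coefficient -> homogeneity holds
  withr::with_seed(65, {
    ev1 <- purrr::map_dfr(names(gen), function(cl) {
      n <- if (cl == "perp") 8000L else 4000L
      tau <- sample_tumble_times(md, n)
      tibble::tibble(psi = abs(rnorm(n, 0, sqrt(2 * 2.3 * tau))),
                     tau = tau, prev_class = cl)
    })
  })
  fits1 <- fit_by_class(ev1, n_boot = 80, seed = 66)
  expect_true(attr(fits1, "homogeneous"))
  expect_true(all(abs(fits1$d_r_hat - 2.3) <= 0.3))
  # all events in one class degenerates to the pooled fit
  fits2 <- suppressMessages(
    fit_by_class(dplyr::mutate(ev1, prev_class = "up"), n_boot = 0)
  )
  expect_equal(fits2$d_r_hat[fits2$class == "up"],
               fits2$d_r_hat[fits2$class == "pooled"])
})
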