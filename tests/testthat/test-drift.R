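# Persistence, translational diffusion and drift metrics

test_that("persistence closed forms match brute-force sums and Monte Carlo", {
  mc <- tumble_time_model("continuous_exponential", 0.14)
  md <- tumble_time_model("discrete_exponential", 0.14, 0.1)
  expect_equal(persistence_from_rotdiff(3.5, mc), 1 / 1.98)
  # discrete closed form: (1-q) e / (1 - q e) with q = 2/7, e = exp(-0.7)
  q <- 2 / 7
  e <- exp(-2 * 3.5 * 0.1)
  expect_equal(persistence_from_rotdiff(3.5, md),
               (1 - q) * e / (1 - q * e))
  # Monte-Carlo oracle for both kinds
  withr::with_seed(71, {
    for (m in list(mc, md)) {
      tau <- sample_tumble_times(m, 4e6)
      x <- exp(-2 * 3.5 * tau)
      expect_true(within_se(persistence_from_rotdiff(3.5, m), mean(x),
                            sd(x) / sqrt(4e6), 3))
    }
  })
  expect_warning(a <- persistence_from_rotdiff(0, md))
  expect_equal(a, 1)
})

test_that("translational diffusion has the closed-form limits and monotonicity", {
  expect_equal(translational_diffusion(20, 1, 0), 400 / 3)
  expect_equal(translational_diffusion(20, 1, 0.33) /
                 translational_diffusion(20, 1, 0), 1 / (1 - 0.33))
  alphas <- seq(-0.5, 0.9, by = 0.1)
  dts <- vapply(alphas, function(a) translational_diffusion(20, 1, a),
                numeric(1))
  expect_true(all(diff(dts) > 0))
  expect_error(translational_diffusion(20, 1, 1),
               class = "rotumble_domain_error")
})

test_that("simulated 3D tracks reproduce the persistent-random-walk closure", {
  # continuous tumbles with a short mean keep the run/tumble duty-cycle
  # correction (neglected by the closure) at the percent level
  model <- tumble_time_model("continuous_exponential", 0.05)
  sc <- run_tumble_scenario(v_run = 20, mean_run = 1, tumble_model = model,
                            d_r = 3.5, mode = "3d", frame_rate = 5,
                            n_tracks = 300, duration = 60, seed = 72)
  sim <- simulate_run_tumble(sc)
  alpha <- persistence_from_rotdiff(3.5, model)
  d_t <- translational_diffusion(20, 1, alpha, dimension = 3)
  # MSD slope between 10 and 50 s, over 6
  msd <- sim$tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      d10 = (x_um[t_s == 10] - x_um[1])^2 + (y_um[t_s == 10] - y_um[1])^2 +
        (z_um[t_s == 10] - z_um[1])^2,
      d50 = (x_um[t_s == 50] - x_um[1])^2 + (y_um[t_s == 50] - y_um[1])^2 +
        (z_um[t_s == 50] - z_um[1])^2,
      .groups = "drop")
  slope <- (mean(msd$d50) - mean(msd$d10)) / 40
  expect_equal(slope / 6, d_t, tolerance = 0.15)
})

test_that("drift estimates behave on deterministic and null inputs", {
  # straight deterministic tracks along the axis -> exactly v
  tr <- purrr::map_dfr(1:12, function(id) {
    tibble::tibble(track_id = id, t_s = seq(0, 10, 0.1),
                   x_um = 7 * seq(0, 10, 0.1), y_um = 0)
  })
  dv <- drift_velocity(tr, c(1, 0))
  expect_equal(dv$v_drift, 7)
  expect_equal(dv$se, 0)
  expect_error(drift_velocity(tr[tr$track_id < 5, ], c(1, 0)),
               class = "rotumble_parameter_error")
  expect_error(drift_velocity(tr, NULL), class = "rotumble_parameter_error")
})

test_that("adding tumble modulation on top of run modulation increases drift", {
  # tumble modulation contributes ~1 um/s on top of the ~1.7 um/s from run
  # modulation; 1200 tracks put the one-sided test at ~3.5 sigma power
  run_only <- simulate_run_tumble(run_tumble_scenario(
    chi_run = 0.25, chi_tumble = 0, gradient_axis = c(1, 0),
    n_tracks = 1200, duration = 20, seed = 73))
  both <- simulate_run_tumble(run_tumble_scenario(
    chi_run = 0.25, chi_tumble = 0.25, gradient_axis = c(1, 0),
    n_tracks = 1200, duration = 20, seed = 74))
  v1 <- drift_velocity(run_only, c(1, 0))
  v2 <- drift_velocity(both, c(1, 0))
  # one-sided comparison at alpha = 0.01
  z <- (v2$v_drift - v1$v_drift) / sqrt(v1$se^2 + v2$se^2)
  expect_gt(z, stats::qnorm(0.99))
  # drift sign is stable across seeds
  signs <- vapply(75:84, function(s) {
    sim <- simulate_run_tumble(run_tumble_scenario(
      chi_run = 0.25, chi_tumble = 0.25, gradient_axis = c(1, 0),
      n_tracks = 60, duration = 20, seed = s))
    drift_velocity(sim, c(1, 0))$v_drift > 0
  }, logical(1))
  expect_true(all(signs))
})

test_that("modulation summary reports all three baselines", {
  fits <- tibble::tibble(class = c("up", "perp", "down", "pooled"),
                         d_r_hat = c(2.3, 3.2, 4.4, 3.2),
                         stderr = 0.1, n_events = 100L, n_bins = 5L,
                         flagged = FALSE)
  class(fits) <- c("rt_class_fits", class(fits))
  ev <- tibble::tibble(tau = rep(c(0.16, 0.14, 0.2), c(100, 100, 100)),
                       prev_class = rep(c("up", "perp", "down"), each = 100))
  ms <- modulation_summary(fits, ev)
  d_r_rows <- ms[ms$quantity == "d_r", ]
  expect_equal(d_r_rows$relative_modulation[d_r_rows$baseline_kind ==
                                              "class_mean"],
               (4.4 - 2.3) / 3.35)
  expect_equal(nrow(ms), 6)
  # tau down/up ratio 1.25 -> ~22% under the class-mean baseline
  tau_row <- ms[ms$quantity == "mean_tau_tumble" &
                  ms$baseline_kind == "class_mean", ]
  expect_equal(tau_row$relative_modulation, (0.2 - 0.16) / 0.18)
  # identical classes -> zero modulation
  fits0 <- dplyr::mutate(fits, d_r_hat = 3)
  class(fits0) <- c("rt_class_fits", class(fits0))
  ev0 <- dplyr::mutate(ev, tau = 0.15)
  ms0 <- modulation_summary(fits0, ev0)
  expect_true(all(ms0$relative_modulation == 0))
  expect_error(modulation_summary(fits[fits$class == "up", ], ev),
               class = "rotumble_parameter_error")
})
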