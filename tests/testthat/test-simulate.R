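# Synthetic run-and-tumble trajectories and tumbler series

test_that("homogeneous scenario reproduces its own kinetic parameters", {
  sc <- run_tumble_scenario(n_tracks = 120, duration = 20, seed = 31)
  sim <- simulate_run_tumble(sc)
  ev <- sim$events
  # censoring by the track end length-biases completed-run durations, so
  # test the uncensored first run of every track against Exp(mean_run)
  first_runs <- ev |>
    dplyr::filter(.data$kind == "run") |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  expect_true(within_se(mean(first_runs$duration), 1,
                        sd(first_runs$duration) / sqrt(nrow(first_runs)), 3))
  expect_gt(stats::ks.test(first_runs$duration, "pexp", 1)$p.value, 0.01)
  tv <- true_events(sim)
  # ground-truth <cos theta> equals the discrete-mixture closed form
  alpha <- persistence_from_rotdiff(2.1, sc$tumble_model)
  expect_true(within_se(mean(cos(tv$theta)), alpha,
                        sd(cos(tv$theta)) / sqrt(nrow(tv)), 3))
  # observed planar turn at fixed duration follows the projected law
  e1 <- tv[abs(tv$tau - 0.1) < 1e-9, ]
  expect_true(within_se(mean(cos(e1$psi)),
                        projected_autocorrelation(0.1, 2.1)$value,
                        sd(cos(e1$psi)) / sqrt(nrow(e1)), 3))
  # determinism
  sim2 <- simulate_run_tumble(sc)
  expect_identical(sim$tracks, sim2$tracks)
  expect_identical(sim$events, sim2$events)
})

test_that("d_r = 0 yields straight tracks with pauses and zero reorientation", {
  sc <- run_tumble_scenario(d_r = 0, n_tracks = 3, duration = 10, seed = 32)
  sim <- simulate_run_tumble(sc)
  tv <- true_events(sim)
  expect_true(all(tv$theta == 0))
  expect_true(all(tv$psi == 0))
  # every track is collinear: displacement directions all parallel
  for (df in split(sim$tracks, sim$tracks$track_id)) {
    dx <- diff(df$x_um); dy <- diff(df$y_um)
    keep <- dx^2 + dy^2 > 1e-12
    cr <- dx[keep][1] * dy[keep] - dy[keep][1] * dx[keep]
    expect_lt(max(abs(cr)), 1e-6)
  }
})

test_that("run modulation lengthens up-gradient runs and biases drift", {
  sc <- run_tumble_scenario(chi_run = 0.3, gradient_axis = c(1, 0),
                            n_tracks = 250, duration = 20, seed = 33)
  sim <- simulate_run_tumble(sc)
  runs <- sim$events[sim$events$kind == "run" & sim$events$complete, ]
  cosphi <- runs$dir_x
  up <- runs$duration[cosphi > 0.7]
  down <- runs$duration[cosphi < -0.7]
  ratio <- mean(up) / mean(down)
  expected <- (1 + 0.3 * mean(cosphi[cosphi > 0.7])) /
    (1 + 0.3 * mean(cosphi[cosphi < -0.7]))
  expect_equal(ratio, expected, tolerance = 0.1)
  dv <- drift_velocity(sim, c(1, 0))
  expect_gt(dv$v_drift, 3 * dv$se)
})

test_that("tumble-duration modulation alone produces positive drift", {
  sc <- run_tumble_scenario(chi_run = 0, chi_tumble = 0.28,
                            gradient_axis = c(1, 0), n_tracks = 400,
                            duration = 20, seed = 34)
  sim <- simulate_run_tumble(sc)
  # tumbles after up-gradient runs are shorter on average
  tv <- true_events(sim)
  expect_lt(mean(tv$tau[tv$prev_class == "up"]),
            mean(tv$tau[tv$prev_class == "down"]))
  dv <- drift_velocity(sim, c(1, 0))
  expect_gt(dv$v_drift, 3 * dv$se)
})

test_that("no-gradient scenarios are drift-free along every axis", {
  sim <- simulate_run_tumble(run_tumble_scenario(n_tracks = 200,
                                                 duration = 20, seed = 35))
  for (ax in list(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))) {
    dv <- drift_velocity(sim, ax)
    expect_true(within_se(dv$v_drift, 0, dv$se, 3))
  }
})

test_that("3d mode is isotropic and its projection obeys the isotropic3d law", {
  sc <- run_tumble_scenario(mode = "3d", d_r = 1, n_tracks = 150,
                            duration = 20, seed = 36)
  sim <- simulate_run_tumble(sc)
  runs <- sim$events[sim$events$kind == "run", ]
  expect_gt(stats::ks.test(runs$dir_z[!is.na(runs$dir_z)],
                           "punif", -1, 1)$p.value, 0.01)
  pr <- project_to_plane(sim)
  ev <- pr$events[abs(pr$events$tau - 0.1) < 1e-9, ]
  v <- projected_autocorrelation(0.1, 1, reference = "isotropic3d")$value
  expect_true(within_se(mean(cos(ev$psi)), v,
                        sd(cos(ev$psi)) / sqrt(nrow(ev)), 3))
  # swapping to an orthogonal observation plane leaves statistics unchanged
  pr2 <- project_to_plane(sim, plane_normal = c(1, 0, 0))
  m1 <- mean(cos(pr$events$psi)); m2 <- mean(cos(pr2$events$psi))
  se <- sqrt(sd(cos(pr$events$psi))^2 + sd(cos(pr2$events$psi))^2) /
    sqrt(nrow(pr$events))
  expect_true(within_se(m1, m2, se, 3))
})

test_that("planar-mode projection onto the optical axis is congruent", {
  sim <- simulate_run_tumble(run_tumble_scenario(n_tracks = 5, duration = 10,
                                                 seed = 37))
  pr <- project_to_plane(sim)
  expect_equal(pr$tracks$x_um, sim$tracks$x_um)
  expect_equal(pr$tracks$y_um, sim$tracks$y_um)
  expect_error(project_to_plane(sim, c(1, 1, 0)),
               class = "rotumble_domain_error")
})

test_that("scenario validation rejects broken modulations", {
  expect_error(run_tumble_scenario(chi_run = 1.2),
               class = "rotumble_parameter_error")
  expect_error(run_tumble_scenario(chi_tumble = 0.5),
               class = "rotumble_parameter_error") # 0.14 * 0.5 < 0.1
  expect_error(run_tumble_scenario(n_tracks = 0),
               class = "rotumble_parameter_error")
  expect_error(run_tumble_scenario(d_r_by_class = list(up = 1)),
               class = "rotumble_parameter_error")
})

test_that("tumbler series follow the planar diffusion observation model", {
  # constant at d_r = 0
  s0 <- simulate_tumbler(0, duration = 2, n_cells = 2, seed = 41)
  expect_equal(sd(s0$psi_rad[s0$cell_id == 1]), 0)
  # increment variance = 2 d_r dt at 50 fps
  s <- simulate_tumbler(2.4, duration = 20, n_cells = 20, seed = 42)
  inc <- unlist(lapply(split(s$psi_rad, s$cell_id), diff), use.names = FALSE)
  expect_equal(var(inc), 2 * 2.4 * 0.02, tolerance = 0.05)
  # autocorrelation consistent with exp(-d_r tau) up to 0.5 s
  cv <- orientation_autocorrelation(s, max_lag = 0.5)
  expect_true(all(abs(cv$mean_cos - exp(-2.4 * cv$tau)) <= 3 * cv$se))
  # aliasing warning
  expect_warning(simulate_tumbler(100, frame_rate = 20, duration = 1,
                                  n_cells = 1, seed = 43))
})
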