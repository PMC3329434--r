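# Segmentation, event extraction and correlation curves

make_straight_track <- function(n = 50, v = 20, fps = 10) {
  t <- (seq_len(n) - 1) / fps
  tibble::tibble(t_s = t, x_um = v * t, y_um = 0)
}

test_that("a straight constant-speed track is a single run", {
  seg <- segment_track(make_straight_track())
  expect_equal(nrow(seg), 1)
  expect_equal(seg$kind, "run")
  expect_equal(c(seg$dir_x, seg$dir_y), c(1, 0))
})

test_that("input validation: shuffled frames, non-uniform sampling, short tracks", {
  tr <- make_straight_track()
  expect_error(segment_track(tr[sample.int(nrow(tr)), ]),
               class = "rotumble_domain_error")
  tr2 <- tr
  tr2$t_s[10] <- tr2$t_s[10] + 0.03
  expect_error(segment_track(tr2), class = "rotumble_domain_error")
  expect_error(segment_track(tr[1:5, ]), class = "rotumble_short_track")
  expect_message(segment_tracks(dplyr::bind_rows(
    dplyr::mutate(tr, track_id = 1),
    dplyr::mutate(tr[1:5, ], track_id = 2)
  )), "skipped")
})

test_that("segmentation recovers ground-truth tumbles at default settings", {
  sim <- simulate_run_tumble(run_tumble_scenario(n_tracks = 150,
                                                 duration = 20, seed = 51))
  tv <- true_events(sim)
  segs <- segment_tracks(project_to_plane(sim))
  det <- segs[segs$kind == "tumble", ]
  det_by_track <- split(det, det$track_id)
  matched <- 0L
  boundary_ok <- 0L
  for (i in seq_len(nrow(tv))) {
    d <- det_by_track[[as.character(tv$track_id[i])]]
    if (is.null(d)) next
    t0 <- tv$t_start[i]; t1 <- t0 + tv$tau[i]
    ov <- pmin(d$t_end, t1) - pmax(d$t_start, t0)
    j <- which.max(ov)
    if (length(j) == 1L && ov[j] > 0) {
      matched <- matched + 1L
      if (abs(d$t_start[j] - t0) <= 0.1 + 1e-9 &&
          abs(d$t_end[j] - t1) <= 0.1 + 1e-9) {
        boundary_ok <- boundary_ok + 1L
      }
    }
  }
  expect_gte(matched / nrow(tv), 0.80)
  expect_gte(boundary_ok / nrow(tv), 0.80)
  ev <- reorientation_events(segs)
  expect_lt(abs(mean(ev$tau) - mean(tv$tau)) / mean(tv$tau), 0.20)
  # matched (psi, tau) joint distribution: detected psi tracks truth
  det_ev <- ev |> dplyr::mutate(key = paste(track_id, round(t_start, 1)))
  tru_ev <- tv |> dplyr::mutate(key = paste(track_id, round(t_start, 1)))
  m <- dplyr::inner_join(det_ev, tru_ev, by = "key",
                         suffix = c("_det", "_tru"))
  expect_gt(nrow(m), 0.5 * nrow(tv))
  expect_gte(stats::cor(m$psi_det, m$psi_tru), 0.9)
})

test_that("quadrant classification uses half-open 45-degree cones", {
  mk <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
  cls <- function(deg) {
    d <- mk(deg)
    rotumble:::classify_direction_2d(d[1], d[2], c(1, 0))
  }
  expect_equal(cls(44), "up")
  expect_equal(cls(45), "perp")
  expect_equal(cls(46), "perp")
  expect_equal(cls(135), "perp")
  expect_equal(cls(136), "down")
  expect_equal(cls(180), "down")
  expect_equal(cls(-44), "up")
  # partition: every direction maps to exactly one class, cones subtend 90deg
  degs <- seq(0, 359.5, by = 0.5)
  classes <- vapply(degs, cls, character(1))
  expect_true(all(classes %in% c("up", "down", "perp")))
  expect_equal(sum(classes == "up") / length(classes), 0.25, tolerance = 0.01)
  expect_equal(sum(classes == "down") / length(classes), 0.25,
               tolerance = 0.01)
})

test_that("collinear runs give psi = 0 and zero-length runs are dropped", {
  # run - pause - run, all along +x
  t <- seq(0, 4.9, by = 0.1)
  x <- c(seq(0, 2, by = 0.1) * 20, rep(40, 9), 40 + seq(0.1, 2, by = 0.1) * 20)
  tr <- tibble::tibble(t_s = t, x_um = x, y_um = 0)
  seg <- segment_track(tr)
  ev <- reorientation_events(seg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$psi, 0)
  expect_equal(ev$prev_class, "none")
})

test_that("correlation curves are correct, suppressed below min_count, and refuse empties", {
  ev <- tibble::tibble(psi = rep(0, 40), tau = rep(0.1, 40))
  cv <- correlation_curve(ev)
  expect_equal(cv$mean_cos, 1)
  expect_equal(cv$n, 40L)
  # model events at d_r = 2.1: curve within 3 SE of the projected law
  md <- tumble_time_model("discrete_exponential", 0.14, 0.1)
  withr::with_seed(52, {
    tau <- sample_tumble_times(md, 20000)
    psi <- abs(rnorm(20000, 0, sqrt(2 * 2.1 * tau)))
  })
  cv2 <- correlation_curve(tibble::tibble(psi = psi, tau = tau))
  expect_true(all(abs(cv2$mean_cos -
                        projected_autocorrelation(cv2$tau, 2.1)$value) <=
                    3 * cv2$se))
  expect_true(all(cv2$n >= 10))
  # single populated bin -> fit must refuse
  one <- correlation_curve(tibble::tibble(psi = runif(30), tau = 0.1))
  expect_equal(nrow(one), 1)
  expect_error(fit_exponential(one), class = "rotumble_parameter_error")
  expect_error(correlation_curve(ev[0, ]), class = "rotumble_parameter_error")
})

test_that("orientation autocorrelation handles closed-form cases", {
  # constant angle -> 1 at all lags
  s1 <- tibble::tibble(cell_id = 1, t_s = seq(0, 10, 0.02), psi_rad = 1.3)
  cv <- orientation_autocorrelation(s1, max_lag = 0.5)
  expect_true(all(cv$mean_cos == 1))
  expect_true(all(is.na(cv$se)))
  # uniform rotation omega -> cos(omega tau)
  s2 <- tibble::tibble(cell_id = 1, t_s = seq(0, 10, 0.02),
                       psi_rad = 2 * seq(0, 10, 0.02))
  cv2 <- orientation_autocorrelation(s2, max_lag = 1)
  expect_equal(cv2$mean_cos, cos(2 * cv2$tau), tolerance = 1e-9)
  expect_error(orientation_autocorrelation(s2, max_lag = 20),
               class = "rotumble_parameter_error")
})
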