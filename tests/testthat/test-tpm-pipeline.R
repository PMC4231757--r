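test_that("drift filter removes offsets and ramps but spares tether motion", {
  n <- 25 * 120
  t <- (0:(n - 1)) / 25
  const <- tpm_trajectory(t, rep(100, n), rep(-40, n))
  filt <- drift_filter(const, 20)
  expect_equal(max(abs(filt$x)), 0)
  expect_equal(max(abs(filt$y)), 0)
  expect_error(drift_filter(const, 0), "positive")

  # linear 1 nm/s drift: interior residual is tiny versus the accumulated drift
  ramp <- tpm_trajectory(t, t * 1.0, rep(0, n))
  rf <- drift_filter(ramp, 20)
  interior <- seq(25 * 20, n - 25 * 20)
  accumulated <- max(t)
  expect_lt(max(abs(rf$x[interior])), 0.01 * accumulated)
  expect_gt(attr(rf, "drift_removed_nm"), 0)

  # fast zero-mean tether motion is left nearly untouched
  cfg <- tpm_sim_config(model = base_model(), duration = 300, seed = 5)
  traj <- simulate_tpm(cfg)
  r_raw <- mean(windowed_rms(traj, 4)$rms)
  r_filt <- mean(windowed_rms(drift_filter(traj, 20), 4)$rms)
  expect_lt(abs(r_filt / r_raw - 1), 0.03)
})

test_that("windowed RMS reproduces closed-form cases and is translation invariant", {
  n <- 25 * 60
  t <- (0:(n - 1)) / 25
  const <- tpm_trajectory(t, rep(7, n), rep(-3, n))
  expect_equal(max(windowed_rms(const, 4)$rms), 0)

  # circular motion of radius a: rms -> a when the window covers whole turns
  a <- 508
  circ <- tpm_trajectory(t, a * cos(2 * pi * t), a * sin(2 * pi * t))
  expect_equal(mean(windowed_rms(circ, 4)$rms), a, tolerance = 1e-6)

  # iid Gaussian per axis: rms -> sigma * sqrt(2)
  set.seed(31)
  sigma <- 120
  gaus <- tpm_trajectory(t, rnorm(n, sd = sigma), rnorm(n, sd = sigma))
  expect_equal(mean(windowed_rms(gaus, 4)$rms), sigma * sqrt(2),
               tolerance = 0.03)

  shifted <- tpm_trajectory(t, gaus$x + 1234, gaus$y - 987)
  expect_equal(windowed_rms(shifted, 4)$rms, windowed_rms(gaus, 4)$rms)

  rs <- windowed_rms(gaus, 4)
  expect_length(rs$rms, n - 100 + 1)
  short <- tpm_trajectory(t[1:50], gaus$x[1:50], gaus$y[1:50])
  expect_error(windowed_rms(short, 4), "shorter than one window")
  expect_error(windowed_rms(gaus, 0.04), "at least 2 samples")
})

test_that("circularity screen separates isotropic from anisotropic motion", {
  set.seed(41)
  n <- 6000
  t <- (0:(n - 1)) / 25
  iso <- tpm_trajectory(t, rnorm(n, sd = 100), rnorm(n, sd = 100))
  rep_iso <- circularity_screen(iso)
  expect_true(rep_iso$passed)
  expect_gt(rep_iso$circularity, 0.9)

  # 20% axis anisotropy: circularity ~ 1/1.2, deviation ~ 16.7% -> fails at 10%
  ani <- tpm_trajectory(t, rnorm(n, sd = 120), rnorm(n, sd = 100))
  rep_ani <- circularity_screen(ani)
  expect_false(rep_ani$passed)
  expect_equal(rep_ani$circularity, 1 / 1.2, tolerance = 0.05)

  # strictly 1-D motion is degenerate and fails with a note, not an error
  flat <- tpm_trajectory(t, rnorm(n, sd = 100), rep(0, n))
  rep_flat <- circularity_screen(flat)
  expect_false(rep_flat$passed)
  expect_equal(rep_flat$circularity, 0)
  zero <- tpm_trajectory(t, rep(0, n), rep(0, n))
  rep_zero <- circularity_screen(zero)
  expect_false(rep_zero$passed)
  expect_match(rep_zero$note, "degenerate")
})

test_that("circularity is invariant under rotations of the camera frame", {
  set.seed(43)
  n <- 4000
  t <- (0:(n - 1)) / 25
  x <- rnorm(n, sd = 130)
  y <- rnorm(n, sd = 100)
  base <- circularity_screen(tpm_trajectory(t, x, y))$circularity
  for (theta in runif(5, 0, 2 * pi)) {
    xr <- cos(theta) * x - sin(theta) * y
    yr <- sin(theta) * x + cos(theta) * y
    rot <- circularity_screen(tpm_trajectory(t, xr, yr))$circularity
    expect_equal(rot, base, tolerance = 1e-10)
  }
})

test_that("stuck-event detector flags steps but not smooth collapse", {
  t <- seq(2, 600, by = 0.04)
  expect_equal(nrow(detect_stuck_events(rms_series(t, rep(500, length(t)), 4))),
               0)
  # discrete step 500 -> 100 nm at t = 60 s that persists
  step <- ifelse(t < 60, 500, 100)
  ev <- detect_stuck_events(rms_series(t, step, 4))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time - 60), 3)
  expect_gt(ev$magnitude, 300)
  # smooth exponential collapse (tau = 7.5 min) must NOT be flagged
  dec <- 200 + 300 * exp(-t / 450)
  expect_equal(nrow(detect_stuck_events(rms_series(t, dec, 4))), 0)

  masked <- mask_stuck_events(rms_series(t, step, 4), ev)
  expect_true(all(is.na(masked$rms[t > 70])))
  expect_true(all(!is.na(masked$rms[t < 50])))
})

test_that("screen_trajectory consolidates circularity, drift and stuck events", {
  cfg <- tpm_sim_config(model = base_model(), duration = 300,
                        stuck = list(time = 150, residual_fraction = 0.2),
                        drift = list(amplitude = 200, type = "linear"),
                        seed = 77)
  rep <- screen_trajectory(simulate_tpm(cfg, bead_id = "s1"))
  expect_s3_class(rep, "screen_report")
  expect_gte(nrow(rep$stuck_events), 1)
  expect_lt(abs(rep$stuck_events$time[1] - 150), 10)
  expect_gt(rep$drift_removed_nm, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_screen_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$bead_id, "s1")
  expect_true(is.numeric(parsed$circularity))
})

test_that("persistence length is recovered from simulated stationary tethers", {
  lc <- contour_length_from_bp(5092)
  for (xi_true in c(54, 150)) {
    cfg <- tpm_sim_config(model = base_model(xi_true), duration = 600,
                          seed = 60 + xi_true)
    est <- persistence_from_trajectory(simulate_tpm(cfg), lc, 500)
    expect_lt(abs(est$xi / xi_true - 1), 0.10)
    expect_true(est$stationary)
    expect_gt(est$se, 0)
  }
})

test_that("a degenerate single-window record at the measured RMS gives the printed persistence length", {
  # circular motion of radius 508 nm has windowed RMS exactly 508
  t <- (0:99) / 25
  traj <- tpm_trajectory(t, 508 * cos(2 * pi * t), 508 * sin(2 * pi * t))
  est <- persistence_from_trajectory(traj, contour_length_from_bp(5092), 500,
                                     bias_correction = FALSE)
  expect_equal(est$n_windows, 1)
  expect_lt(abs(est$xi - 54), 5)
})

test_that("a collapse in progress is flagged non-stationary", {
  cfg <- tpm_sim_config(model = base_model(), rms0 = 500, duration = 900,
                        collapse = list(tau_min = 7.5, plateau_fraction = 0.4),
                        seed = 99)
  expect_warning(
    est <- persistence_from_trajectory(simulate_tpm(cfg),
                                       contour_length_from_bp(5092), 500),
    "stationary")
  expect_false(est$stationary)
})

test_that("full pipeline recovers the persistence length across stiffness regimes", {
  lc <- contour_length_from_bp(5092)
  dir <- withr::local_tempdir()
  for (xi_true in c(30, 54, 100, 200)) {
    cfg <- tpm_sim_config(model = base_model(xi_true), duration = 600,
                          drift = list(amplitude = 100, type = "linear"),
                          seed = 500 + xi_true)
    path <- file.path(dir, sprintf("xi%d.csv", xi_true))
    write_trajectory(simulate_tpm(cfg), path)
    traj <- read_trajectory(path)
    filt <- drift_filter(traj, 20)
    expect_true(circularity_screen(filt)$passed)
    est <- persistence_from_trajectory(filt, lc, 500)
    expect_lt(abs(est$xi / xi_true - 1), 0.10)
  }
})

test_that("circularity screening has the required specificity and sensitivity", {
  m <- base_model()
  pass_iso <- vapply(1:100, function(s) {
    cfg <- tpm_sim_config(model = m, duration = 240, seed = 10000 + s)
    circularity_screen(drift_filter(simulate_tpm(cfg), 20))$passed
  }, logical(1))
  expect_gte(sum(pass_iso), 95)
  pass_ani <- vapply(1:100, function(s) {
    cfg <- tpm_sim_config(model = m, duration = 240, anisotropy = c(1.2, 1),
                          seed = 20000 + s)
    circularity_screen(drift_filter(simulate_tpm(cfg), 20))$passed
  }, logical(1))
  expect_gte(sum(!pass_ani), 95)
})
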