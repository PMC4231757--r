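test_that("simulator configs validate their fields", {
  m <- base_model()
  expect_error(tpm_sim_config(), "model or rms0")
  expect_error(tpm_sim_config(model = m, duration = 0))
  expect_error(tpm_sim_config(model = m, collapse = list(tau_min = -1,
                                                         plateau_fraction = 0.4)))
  expect_error(tpm_sim_config(model = m, collapse = list(tau_min = 5,
                                                         plateau_fraction = 1.5)))
  expect_error(tpm_sim_config(model = m, stuck = list(time = 10,
                                                      residual_fraction = 1.2)))
  expect_error(fx_sim_config(m, grid = c(0.5, 0.4, 0.9)))
  expect_error(fx_sim_config(m, grid = c(0.1, 0.5, 1.0)))
  expect_error(fx_sim_config(m, noise_sd = -1))
})

test_that("stationary trajectories reproduce the closed-form excursion law", {
  sets <- expand.grid(xi = c(30, 54, 100, 150, 250),
                      R = c(0, 500))
  for (i in seq_len(nrow(sets))) {
    m <- tether_model(contour_length_from_bp(5092), sets$xi[i],
                      bead_radius = sets$R[i])
    cfg <- tpm_sim_config(model = m, duration = 4000, seed = 900 + i)
    traj <- simulate_tpm(cfg)
    emp <- sqrt(mean((traj$x - mean(traj$x))^2 + (traj$y - mean(traj$y))^2))
    expect_lt(abs(emp / rms_from_persistence(m) - 1), 0.02)
  }
})

test_that("simulated axes have the configured correlation time", {
  cfg <- tpm_sim_config(model = base_model(), duration = 600, tau_c = 0.1,
                        seed = 4)
  traj <- simulate_tpm(cfg)
  est_tau <- function(v) {
    v <- v - mean(v)
    rho <- sum(v[-1] * v[-length(v)]) / sum(v^2)
    -(1 / traj$sample_rate) / log(rho)
  }
  expect_lt(abs(est_tau(traj$x) / 0.1 - 1), 0.10)
  expect_lt(abs(est_tau(traj$y) / 0.1 - 1), 0.10)
})

test_that("the seed fixes the full output stream", {
  cfg <- tpm_sim_config(model = base_model(), duration = 30,
                        drift = list(amplitude = 50, type = "random_walk"),
                        seed = 123)
  a <- simulate_tpm(cfg)
  b <- simulate_tpm(cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  fxc <- fx_sim_config(base_model(), noise_sd = 0.2, seed = 5)
  expect_identical(simulate_fx(fxc)$f, simulate_fx(fxc)$f)
})

test_that("no-collapse records are stationary and zero-amplitude records are still", {
  for (s in 1:4) {
    cfg <- tpm_sim_config(model = base_model(), duration = 900, seed = 70 + s)
    rs <- windowed_rms(simulate_tpm(cfg), 4)
    half <- length(rs$rms) %/% 2
    m1 <- mean(rs$rms[1:half])
    m2 <- mean(rs$rms[(half + 1):length(rs$rms)])
    expect_lt(abs(m1 - m2) / mean(c(m1, m2)), 0.05)
  }
  still <- simulate_tpm(tpm_sim_config(rms0 = 0, duration = 10, seed = 2))
  expect_equal(max(abs(still$x)), 0)
  expect_equal(max(abs(still$y)), 0)
})

test_that("collapse, stuck and anisotropy options shape the trajectory as configured", {
  m <- base_model()
  cfg <- tpm_sim_config(model = m, rms0 = 500, duration = 1800,
                        collapse = list(tau_min = 7.5, plateau_fraction = 0.4),
                        seed = 31)
  rs <- smooth_running_window(windowed_rms(simulate_tpm(cfg), 4), 60)
  fit <- fit_exponential_decay(rs)
  expect_lt(abs(fit$tau_min / 7.5 - 1), 0.25)  # single trajectory, noisy

  stuckcfg <- tpm_sim_config(model = m, rms0 = 500, duration = 600,
                             stuck = list(time = 300, residual_fraction = 0.2),
                             seed = 32)
  ev <- detect_stuck_events(windowed_rms(simulate_tpm(stuckcfg), 4))
  expect_gte(nrow(ev), 1)
  expect_lt(abs(ev$time[1] - 300), 10)

  anicfg <- tpm_sim_config(model = m, duration = 600, anisotropy = c(1.2, 1),
                           seed = 33)
  traj <- simulate_tpm(anicfg)
  expect_equal(sd(traj$x) / sd(traj$y), 1.2, tolerance = 0.05)
})

test_that("noiseless force-extension sweeps lie exactly on the WLC curve", {
  m <- tether_model(1731.3, 53)
  curve <- simulate_fx(fx_sim_config(m, noise_sd = 0))
  expect_equal(curve$f, wlc_force(curve$z, m), tolerance = 1e-12)
  expect_true(all(diff(curve$z) < 0))  # down sweep: high force to low
})

test_that("shrink schedules emit one curve per time and are recoverable", {
  m <- tether_model(1731, 53)
  sched <- data.frame(t_s = c(0, 120), Lc_nm = c(1731, 1386))
  curves <- simulate_fx(fx_sim_config(m, noise_sd = 0.1,
                                      shrink_schedule = sched, seed = 9))
  expect_length(curves, 2)
  expect_equal(vapply(curves, `[[`, numeric(1), "timestamp"), c(0, 120))
  fits <- lapply(curves, fit_wlc_free_lc)
  ratio <- fits[[2]]$Lc / fits[[1]]$Lc
  expect_lt(abs(ratio - 0.80), 0.02)
  # an absolute grid must stay below every scheduled contour length
  expect_error(fx_sim_config(m, shrink_schedule = sched,
                             grid_mode = "absolute"),
               "exceeds")
  ok <- fx_sim_config(m, grid = seq(0.1, 0.7, length.out = 20),
                      shrink_schedule = sched, grid_mode = "absolute",
                      seed = 10)
  curves_abs <- simulate_fx(ok)
  expect_equal(curves_abs[[1]]$z, curves_abs[[2]]$z)
})

test_that("the fixture suite is deterministic and self-describing", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- make_fixture_suite(d1, seed = 3, duration = 30, n_collapse = 2,
                             n_control = 1)
  man2 <- make_fixture_suite(d2, seed = 3, duration = 30, n_collapse = 2,
                             n_control = 1)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  f <- man1$ensembles$hha_hns_100nM$files[1]
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_equal(man1$ensembles$hha_hns_100nM$tau_min, 7.5)
  expect_equal(man1$ensembles$hha_hns_200nM$tau_min, 7.3)
  expect_equal(man1$ensembles$hha_hns_200nM$plateau_fraction, 0.15)
  traj <- read_trajectory(file.path(d1, f))
  expect_s3_class(traj, "tpm_trajectory")
  expect_error(make_fixture_suite(""), "non-empty")
})
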