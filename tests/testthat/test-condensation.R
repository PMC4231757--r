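test_that("running-window smoothing has the right impulse and dc response", {
  t <- seq(0, 300, by = 0.5)
  const <- rms_series(t, rep(321, length(t)), window = 4)
  expect_equal(smooth_running_window(const, 60)$rms, const$rms)

  imp <- rep(0, length(t))
  imp[301] <- 1
  sm <- smooth_running_window(rms_series(t, imp, window = 4), 60)
  n_w <- 121  # 60 s at 0.5 s spacing, centred
  expect_equal(max(sm$rms), 1 / n_w, tolerance = 1e-10)
  expect_equal(sum(sm$rms > 0), n_w)
  expect_error(smooth_running_window(const, -1), "positive")

  # long stationary segments keep their mean
  set.seed(9)
  noisy <- rms_series(t, 400 + rnorm(length(t), sd = 15), window = 4)
  sm2 <- smooth_running_window(noisy, 60)
  expect_lt(abs(mean(sm2$rms) / mean(noisy$rms) - 1), 0.001)
})

test_that("smoothing a slow exponential barely biases the fitted time constant", {
  t <- seq(0, 1800, by = 0.25)
  r <- 200 + 300 * exp(-t / 450)
  tau_plain <- fit_exponential_decay(rms_series(t, r, window = 4))$tau_min
  tau_smooth <- fit_exponential_decay(
    smooth_running_window(rms_series(t, r, window = 4), 60))$tau_min
  expect_lt(abs(tau_smooth / 7.5 - 1), 0.02)
  expect_lt(abs(tau_plain / 7.5 - 1), 1e-6)
})

test_that("ensemble average is the pointwise mean with per-point counts", {
  t <- seq(0, 10, by = 0.5)
  a <- rms_series(t, rep(400, length(t)), window = 4)
  b <- rms_series(t, rep(200, length(t)), window = 4)
  avg <- ensemble_average(aligned_ensemble(list(a, b), condition = "c"))
  expect_equal(avg$rms, rep(300, length(t)))
  expect_equal(attr(avg, "count"), rep(2L, length(t)))
  same <- ensemble_average(aligned_ensemble(list(a, a), condition = "c"))
  expect_equal(same$rms, a$rms)
  expect_error(aligned_ensemble(list(), condition = "c"))
})

test_that("averaging reduces pointwise noise roughly as sqrt(n)", {
  series <- sim_ensemble_series(seed = 3, tau_min = 7.5, plateau = 0.4,
                                n = 10, duration = 600)
  avg <- ensemble_average(aligned_ensemble(series, condition = "c"))
  resid_one <- series[[1]]$rms - avg$rms
  # compare scatter of one member around the mean with the scatter of the
  # mean around the fitted trend
  fit <- fit_exponential_decay(avg)
  trend <- fit$Rinf + (fit$R0 - fit$Rinf) * exp(-avg$t / (fit$tau_min * 60))
  ratio <- sd(resid_one) / sd(avg$rms - trend)
  expect_gt(ratio, 2)
  expect_lt(ratio, 6)
})

test_that("exponential decay fit recovers exact parameters and flags flat data", {
  t <- seq(0, 1800, by = 2)
  r <- 200 + 300 * exp(-t / 450)
  fit <- fit_exponential_decay(rms_series(t, r, window = 4))
  expect_equal(fit$R0, 500, tolerance = 1e-6)
  expect_equal(fit$Rinf, 200, tolerance = 1e-6)
  expect_equal(fit$tau_min, 7.5, tolerance = 1e-6)
  expect_true(fit$identifiable)

  set.seed(12)
  flat <- fit_exponential_decay(
    rms_series(t, rep(480, length(t)) + rnorm(length(t), sd = 10), window = 4))
  expect_false(flat$identifiable)
  expect_match(flat$flag, "unresolved|amplitude|exceeds")
  expect_error(fit_exponential_decay(rms_series(1:5, rep(1, 5), window = 4)),
               "at least 10")
})

test_that("zero-offset decay variant fits a pure exponential", {
  t <- seq(0, 1800, by = 2)
  r <- 500 * exp(-t / 450)
  fit <- fit_exponential_decay(rms_series(t, r, window = 4), zero_offset = TRUE)
  expect_equal(fit$R0, 500, tolerance = 1e-6)
  expect_equal(fit$Rinf, 0)
  expect_equal(fit$tau_min, 7.5, tolerance = 1e-6)
})

test_that("collapse time constants are recovered from simulated ensembles", {
  taus <- vapply(1:5, function(seed) {
    series <- sim_ensemble_series(seed, tau_min = 7.5, plateau = 0.4)
    fit_exponential_decay(
      ensemble_average(aligned_ensemble(series, condition = "100nM")))$tau_min
  }, numeric(1))
  expect_lt(abs(median(taus) / 7.5 - 1), 0.10)
})

test_that("no-collapse ensembles are never assigned a confident time constant", {
  idents <- vapply(1:25, function(seed) {
    series <- sim_ensemble_series(seed, n = 8, duration = 900)
    fit_exponential_decay(
      ensemble_average(aligned_ensemble(series, condition = "ctl")))$identifiable
  }, logical(1))
  expect_false(any(idents))
})

test_that("Gaussian histogram fit recovers pooled late-time statistics", {
  set.seed(77)
  t <- seq(0, 30 * 60, by = 2)
  mk <- function() rms_series(t, pmax(rnorm(length(t), 170, 20), 0), window = 4)
  ens <- aligned_ensemble(list(mk(), mk()), condition = "200nM")
  hf <- histogram_gaussian_fit(ens, from_min = 15)
  se <- 20 / sqrt(hf$n)
  expect_lt(abs(hf$mean - 170), 3 * se + 1)
  expect_equal(hf$sigma, 20, tolerance = 0.15)
  expect_true(is.na(hf$flag))

  ident <- aligned_ensemble(list(rms_series(t, rep(170, length(t)), window = 4)),
                            condition = "deg")
  expect_identical(histogram_gaussian_fit(ident)$flag, "degenerate")
  tiny <- aligned_ensemble(list(rms_series(seq(0, 10, 2), rnorm(6, 170, 5),
                                           window = 4)), condition = "few")
  expect_identical(histogram_gaussian_fit(tiny, from_min = 0)$flag,
                   "insufficient samples")
})

test_that("collapsed-population RMS lands between one half and one third of the control", {
  collapsed <- aligned_ensemble(
    sim_ensemble_series(seed = 6, tau_min = 7.5, plateau = 0.4),
    condition = "100nM")
  control <- aligned_ensemble(sim_ensemble_series(seed = 7, n = 4),
                              condition = "control", control = TRUE)
  hc <- histogram_gaussian_fit(collapsed, from_min = 15)
  h0 <- histogram_gaussian_fit(control, from_min = 15)
  ratio <- hc$mean / h0$mean
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 1 / 2)
})

test_that("compaction ratio is a scale-invariant plateau fraction", {
  t <- seq(0, 1800, by = 2)
  fit <- fit_exponential_decay(
    rms_series(t, 250 + 250 * exp(-t / 450), window = 4))
  expect_equal(compaction_ratio(fit), 0.5, tolerance = 1e-6)
  fit3 <- fit_exponential_decay(
    rms_series(t, 167 + 333 * exp(-t / 450), window = 4))
  expect_equal(compaction_ratio(fit3), 1 / 3, tolerance = 0.01)
  # common rescaling of all RMS values leaves the ratio unchanged
  fit_scaled <- fit_exponential_decay(
    rms_series(t, 3.7 * (250 + 250 * exp(-t / 450)), window = 4))
  expect_equal(compaction_ratio(fit_scaled), compaction_ratio(fit),
               tolerance = 1e-6)
  # a no-collapse control keeps its excursion: ratio ~ 1, with a warning
  series <- sim_ensemble_series(seed = 11, n = 6, duration = 900)
  ctl_fit <- fit_exponential_decay(
    ensemble_average(aligned_ensemble(series, condition = "ctl")))
  expect_warning(ratio <- compaction_ratio(ctl_fit), "flagged")
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("recovered compaction ratios track the simulated plateau depth", {
  for (plateau in c(0.4, 1 / 3)) {
    series <- sim_ensemble_series(seed = 17 + round(10 * plateau),
                                  tau_min = 7.5, plateau = plateau)
    fit <- fit_exponential_decay(
      ensemble_average(aligned_ensemble(series, condition = "c")))
    expect_lt(abs(compaction_ratio(fit) / plateau - 1), 0.10)
  }
})

test_that("saturating concentration trend interpolates persistence estimates", {
  conc <- c(0, 100, 300)
  xi <- 150 - (150 - 54) * exp(-conc / 100)
  tr <- concentration_trend(data.frame(concentration_nM = conc, xi_nm = xi))
  expect_equal(tr$xi0, 54, tolerance = 1e-4)
  expect_equal(tr$xi_inf, 150, tolerance = 1e-4)
  expect_equal(tr$c0, 100, tolerance = 1e-3)

  # anchored at the bare-DNA value when a c = 0 point is included
  set.seed(5)
  conc2 <- c(0, 50, 100, 200, 400)
  xi2 <- 160 - (160 - 54) * exp(-conc2 / 120) + rnorm(5, sd = 1)
  tr2 <- concentration_trend(
    data.frame(concentration_nM = conc2, xi_nm = xi2, condition = "pre"))
  expect_lt(abs(tr2$xi0 - 54), 5)

  flat <- concentration_trend(
    data.frame(concentration_nM = c(0, 100, 200), xi_nm = rep(54, 3)))
  expect_match(flat$flag, "flat")
  expect_equal(flat$xi0, 54)
  expect_error(concentration_trend(
    data.frame(concentration_nM = c(0, 1), xi_nm = c(1, 2))), "3")
})
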