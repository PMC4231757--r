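#' High-pass drift filter for bead trajectories
#'
#' Removes slow stage drift by subtracting a centred moving average (window
#' `cutoff_window`) from each axis. The cutoff window must be longer than the
#' RMS analysis window so genuine tether motion is preserved; with the 4 s
#' RMS window the default is 20 s. The magnitude of the removed low-frequency
#' displacement (RMS about the anchor position) is stored in the
#' `drift_removed_nm` attribute, and the window in `drift_window_s`.
#'
#' @param traj A [tpm_trajectory()].
#' @param cutoff_window Moving-average window, s (> 0).
#' @return A drift-corrected [tpm_trajectory()] (per-axis mean approximately
#'   zero).
#' @export
drift_filter <- function(traj, cutoff_window = 20) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  if (!is.numeric(cutoff_window) || cutoff_window <= 0) {
    stop("cutoff_window must be positive")
  }
  k <- max(2L, round(cutoff_window * traj$sample_rate))
  ma_x <- moving_average(traj$x, k)
  ma_y <- moving_average(traj$y, k)
  out <- tpm_trajectory(traj$t, traj$x - ma_x, traj$y - ma_y,
                        bead_id = traj$bead_id)
  attr(out, "drift_removed_nm") <-
    sqrt(mean((ma_x - mean(traj$x))^2 + (ma_y - mean(traj$y))^2))
  attr(out, "drift_window_s") <- cutoff_window
  out
}

#' Windowed RMS excursion of a trajectory
#'
#' For every dense (stride one frame) window position the in-plane RMS
#' excursion is
#' \deqn{\mathrm{rms} = \sqrt{\langle (x-\bar x_w)^2 + (y-\bar y_w)^2
#'   \rangle_w},}
#' with \eqn{\bar x_w, \bar y_w} the in-window means (`centering = "local"`,
#' the default, which keeps residual drift out of the RMS) or the whole-record
#' means (`centering = "global"`). Output time stamps are window centres; the
#' series has `length(input) - window_span + 1` points.
#'
#' @param traj A [tpm_trajectory()].
#' @param window Window duration, s (default 4; at 25 Hz that is 100 frames).
#' @param centering `"local"` or `"global"` window centring.
#' @return An [rms_series()].
#' @export
windowed_rms <- function(traj, window = 4, centering = c("local", "global")) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  centering <- match.arg(centering)
  nw <- round(window * traj$sample_rate)
  n <- length(traj$t)
  if (nw < 2) stop("window must span at least 2 samples")
  if (nw > n) stop("trajectory shorter than one window")
  x <- traj$x
  y <- traj$y
  if (centering == "global") {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  m <- n - nw + 1L
  i <- seq_len(m)
  csx <- cumsum(c(0, x)); csx2 <- cumsum(c(0, x^2))
  csy <- cumsum(c(0, y)); csy2 <- cumsum(c(0, y^2))
  mx2 <- (csx2[i + nw] - csx2[i]) / nw
  my2 <- (csy2[i + nw] - csy2[i]) / nw
  r2 <- mx2 + my2
  if (centering == "local") {
    mx <- (csx[i + nw] - csx[i]) / nw
    my <- (csy[i + nw] - csy[i]) / nw
    r2 <- r2 - mx^2 - my^2
  }
  rms_series(t = traj$t[i] + (nw - 1) / (2 * traj$sample_rate),
             rms = sqrt(pmax(r2, 0)), window = window, bead_id = traj$bead_id)
}

#' Circularity screen for multiple tethers
#'
#' A singly tethered bead explores an isotropic disc; beads held by several
#' tethers (or stuck near an obstacle) move anisotropically. Circularity is
#' measured as \eqn{\sqrt{\lambda_{minor}/\lambda_{major}}} of the 2x2
#' position covariance (the ratio of the RMS amplitudes along the principal
#' axes, rotation invariant); the bead passes when the deviation from unity,
#' \eqn{1 - circularity}, is at most `threshold` (default 10%). Apply after
#' [drift_filter()]. A degenerate (zero-variance or one-dimensional)
#' trajectory fails with a diagnostic rather than raising an error.
#'
#' @param traj A drift-filtered [tpm_trajectory()].
#' @param threshold Maximum tolerated deviation of circularity from 1.
#' @return An object of class `screen_report` with fields `bead_id`,
#'   `circularity`, `passed`, `note`.
#' @export
circularity_screen <- function(traj, threshold = 0.10) {
  stopifnot(inherits(traj, "tpm_trajectory"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  cv <- stats::cov(cbind(traj$x, traj$y))
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (!all(is.finite(ev)) || ev[1] <= 0) {
    rep <- list(bead_id = traj$bead_id, circularity = 0, passed = FALSE,
                threshold = threshold,
                note = "degenerate trajectory: zero positional variance")
    class(rep) <- "screen_report"
    return(rep)
  }
  circ <- sqrt(max(ev[2], 0) / ev[1])
  rep <- list(bead_id = traj$bead_id, circularity = circ,
              passed = (1 - circ) <= threshold, threshold = threshold,
              note = if (ev[2] <= 0) "degenerate: one-dimensional motion" else NA_character_)
  class(rep) <- "screen_report"
  rep
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screen report '%s': circularity %.3f (threshold %.0f%%) -> %s\n",
              x$bead_id, x$circularity, 100 * x$threshold,
              if (isTRUE(x$passed)) "PASS" else "FAIL"))
  if (!is.null(x$stuck_events) && nrow(x$stuck_events) > 0) {
    cat(sprintf("  %d stuck-bead event(s) at t = %s s\n",
                nrow(x$stuck_events),
                paste(round(x$stuck_events$time, 1), collapse = ", ")))
  }
  if (!is.null(x$drift_removed_nm)) {
    cat(sprintf("  drift removed: %.1f nm RMS\n", x$drift_removed_nm))
  }
  if (!is.na(x$note %||% NA)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Detect discrete stuck-bead events in an RMS series
#'
#' Beads occasionally stick to the surface, producing a rapid step-like drop
#' of the windowed RMS that persists. An event is flagged where the running
#' mean of the RMS over the following `dwell` seconds falls below
#' `1 - drop_fraction` times the running mean over the preceding `dwell`
#' seconds; contiguous flags are merged and the event is timed at the largest
#' drop. A smooth collapse (time constant of minutes) changes the RMS far too
#' slowly over `dwell` to trigger the detector, so condensation is not
#' mistaken for sticking.
#'
#' @param series An [rms_series()].
#' @param drop_fraction Minimum fractional RMS drop (default 0.5).
#' @param dwell Persistence requirement, s (default 10).
#' @return A data frame with columns `time` (s) and `magnitude` (nm); zero
#'   rows when no event is found.
#' @export
detect_stuck_events <- function(series, drop_fraction = 0.5, dwell = 10) {
  stopifnot(inherits(series, "rms_series"),
            drop_fraction > 0, drop_fraction < 1, dwell > 0)
  t <- series$t
  r <- series$rms
  n <- length(r)
  dt <- if (n > 1) stats::median(diff(t)) else Inf
  w <- max(2L, round(dwell / dt))
  if (n < 2L * w + 1L) {
    return(data.frame(time = numeric(0), magnitude = numeric(0)))
  }
  cs <- cumsum(c(0, r))
  idx <- (w + 1L):(n - w + 1L)
  before <- (cs[idx] - cs[idx - w]) / w
  after <- (cs[idx + w] - cs[idx]) / w
  cond <- after < (1 - drop_fraction) * before
  cond[!is.finite(cond)] <- FALSE
  if (!any(cond)) {
    return(data.frame(time = numeric(0), magnitude = numeric(0)))
  }
  rl <- rle(cond)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ev_t <- numeric(0)
  ev_m <- numeric(0)
  for (j in which(rl$values)) {
    span <- starts[j]:ends[j]
    k <- span[which.max(before[span] - after[span])]
    ev_t <- c(ev_t, t[idx[k]])
    ev_m <- c(ev_m, before[k] - after[k])
  }
  # merge events closer than one dwell
  keep <- c(TRUE, diff(ev_t) > dwell)
  data.frame(time = ev_t[keep], magnitude = ev_m[keep])
}

#' Mask stuck-bead spans in an RMS series
#'
#' Sets the RMS to `NA` from each detected event until the series recovers to
#' `1 - drop_fraction` of its pre-event level (or to the end of the record if
#' it never does), yielding a cleaned copy for downstream fitting.
#'
#' @param series An [rms_series()].
#' @param events Data frame from [detect_stuck_events()].
#' @param drop_fraction,dwell Must match the values used for detection.
#' @return An [rms_series()] with masked spans set to `NA`.
#' @export
mask_stuck_events <- function(series, events, drop_fraction = 0.5, dwell = 10) {
  stopifnot(inherits(series, "rms_series"))
  if (nrow(events) == 0) return(series)
  r <- series$rms
  t <- series$t
  for (i in seq_len(nrow(events))) {
    t0 <- events$time[i]
    pre <- mean(r[t >= t0 - dwell & t < t0], na.rm = TRUE)
    span <- which(t >= t0)
    rec <- span[which(r[span] >= (1 - drop_fraction) * pre)[1]]
    end <- if (is.na(rec)) length(r) else rec
    r[span[1]:end] <- NA_real_
  }
  rms_series(t, r, window = series$window, bead_id = series$bead_id)
}

#' Full screening pass for one trajectory
#'
#' Drift-filters the trajectory, applies the circularity screen, computes the
#' windowed RMS and scans it for stuck-bead events, returning a consolidated
#' `screen_report` (circularity, pass flag, stuck events, removed drift).
#'
#' @param traj A raw [tpm_trajectory()].
#' @param threshold Circularity deviation threshold (default 0.10).
#' @param drift_window Drift filter window, s.
#' @param rms_window RMS window, s.
#' @param drop_fraction,dwell Stuck-event detector settings.
#' @return A `screen_report` with `stuck_events` and `drift_removed_nm`
#'   filled in; the filtered trajectory is attached as attribute
#'   `"filtered"`.
#' @export
screen_trajectory <- function(traj, threshold = 0.10, drift_window = 20,
                              rms_window = 4, drop_fraction = 0.5,
                              dwell = 10) {
  filt <- drift_filter(traj, drift_window)
  rep <- circularity_screen(filt, threshold)
  rs <- windowed_rms(filt, rms_window)
  rep$stuck_events <- detect_stuck_events(rs, drop_fraction, dwell)
  rep$drift_removed_nm <- attr(filt, "drift_removed_nm")
  attr(rep, "filtered") <- filt
  rep
}

#' Write a screen report to JSON
#' @param report A `screen_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  payload <- list(
    bead_id = report$bead_id,
    circularity = report$circularity,
    passed = report$passed,
    stuck_events = if (is.null(report$stuck_events)) list() else report$stuck_events,
    drift_removed_nm = report$drift_removed_nm %||% NA_real_)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Persistence length from a screened TPM trajectory
#'
#' Converts the mean windowed RMS excursion of a stationary, drift-filtered
#' trajectory into a persistence length by inverting the Gaussian-chain
#' excursion formula ([persistence_from_rms()]).
#'
#' Because bead positions are correlated over the positional relaxation time,
#' subtracting the in-window mean removes a predictable fraction of the true
#' variance (about \eqn{2\tau_c/T_w} for an exponentially correlated process
#' with correlation time \eqn{\tau_c} inside a window \eqn{T_w}). With
#' `bias_correction = TRUE` (default) the lag-one autocorrelation of the
#' trajectory is estimated and the exact AR(1) deflation factor of the RMS
#' window is divided out before inversion. (A preceding drift filter removes
#' only lower-frequency power whose in-window component the centring
#' subtracts anyway, so no additional factor applies.) The standard error of
#' \eqn{\hat\xi} is propagated from
#' the sampling error of the mean RMS through the local derivative of the
#' excursion formula.
#'
#' Stationarity is asserted by requiring the first-half and second-half mean
#' RMS to agree within `stationarity_tol`; a violation (e.g. a collapse in
#' progress) flags the estimate and raises a warning.
#'
#' @param traj A screened, drift-filtered [tpm_trajectory()].
#' @param contour_length DNA contour length, nm.
#' @param bead_radius Bead radius, nm.
#' @param window RMS window, s.
#' @param bias_correction Apply the finite-window AR(1) deflation correction.
#' @param stationarity_tol Maximum tolerated relative difference between
#'   first- and second-half mean RMS.
#' @return An object of class `persistence_estimate`: fields `xi`, `se`
#'   (nm), `r_rms`, `r_rms_se`, `n_windows`, `stationary`, `rho1`.
#' @export
persistence_from_trajectory <- function(traj, contour_length, bead_radius,
                                        window = 4, bias_correction = TRUE,
                                        stationarity_tol = 0.10) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  rs <- windowed_rms(traj, window)
  r <- rs$rms
  half <- length(r) %/% 2L
  stationary <- TRUE
  if (half >= 1L) {
    m1 <- mean(r[seq_len(half)])
    m2 <- mean(r[(half + 1L):length(r)])
    if (abs(m1 - m2) / mean(c(m1, m2)) > stationarity_tol) {
      stationary <- FALSE
      warning("trajectory is not stationary (first/second half mean RMS ",
              "differ by more than ", 100 * stationarity_tol,
              "%); persistence estimate is unreliable")
    }
  }
  r2 <- mean(r^2)
  rho1 <- NA_real_
  if (bias_correction) {
    xm <- traj$x - mean(traj$x)
    ym <- traj$y - mean(traj$y)
    n <- length(xm)
    num <- sum(xm[-1] * xm[-n]) + sum(ym[-1] * ym[-n])
    den <- sum(xm^2) + sum(ym^2)
    rho1 <- max(min(num / den, 0.9999), 0)
    nw <- round(window * traj$sample_rate)
    # Only the RMS-window deflation is corrected. A preceding drift filter
    # removes strictly lower-frequency power whose in-window component the
    # per-window centring subtracts anyway, so adding its deflation factor
    # would double-count (verified against the generator's stationary law).
    defl <- ar1_var_deflation(rho1, nw)
    if (is.finite(defl) && defl > 0.1) r2 <- r2 / defl
  }
  r_rms <- sqrt(r2)
  n_indep <- max(1, floor((traj$t[length(traj$t)] - traj$t[1]) / window))
  r_se <- stats::sd(r) / sqrt(n_indep)
  xi <- persistence_from_rms(r_rms, contour_length, bead_radius)
  h <- xi * 1e-4
  deriv <- (eq_rms(contour_length, xi + h, bead_radius) -
            eq_rms(contour_length, xi - h, bead_radius)) / (2 * h)
  out <- list(xi = xi, se = r_se / deriv, r_rms = r_rms, r_rms_se = r_se,
              n_windows = length(r), stationary = stationary, rho1 = rho1,
              contour_length = contour_length, bead_radius = bead_radius,
              bead_id = traj$bead_id)
  class(out) <- "persistence_estimate"
  out
}

#' @export
print.persistence_estimate <- function(x, ...) {
  cat(sprintf(
    "Persistence estimate '%s': xi = %.1f +/- %.1f nm (R_RMS = %.1f nm)%s\n",
    x$bead_id, x$xi, x$se, x$r_rms,
    if (!isTRUE(x$stationary)) "  [NON-STATIONARY]" else ""))
  invisible(x)
}
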