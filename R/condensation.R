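#' Release-aligned ensemble of RMS trajectories
#'
#' A set of windowed-RMS series from one experimental condition, aligned so
#' that t = 0 is the moment the bead is released from the optical trap.
#'
#' @param series List of [rms_series()] objects (>= 1).
#' @param condition Condition label (e.g. protein name).
#' @param concentration_nM Protein concentration, nM.
#' @param control Logical: unstretched control population?
#' @return An object of class `aligned_ensemble`.
#' @export
aligned_ensemble <- function(series, condition = "", concentration_nM = NA_real_,
                             control = FALSE) {
  stopifnot(is.list(series), length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "rms_series")))
  structure(list(series = series, condition = condition,
                 concentration_nM = concentration_nM, control = control),
            class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf("Aligned ensemble '%s'%s: %d series%s\n", x$condition,
              if (is.finite(x$concentration_nM))
                sprintf(" (%g nM)", x$concentration_nM) else "",
              length(x$series), if (isTRUE(x$control)) " [control]" else ""))
  invisible(x)
}

#' Smooth an RMS series with a running window
#'
#' Centred moving average over `window` seconds; the window shrinks
#' one-sidedly at the record ends so the output length equals the input
#' length. NA spans (masked stuck events) are ignored within each window.
#'
#' @param series An [rms_series()].
#' @param window Smoothing window, s (default 60).
#' @return A smoothed [rms_series()].
#' @export
smooth_running_window <- function(series, window = 60) {
  stopifnot(inherits(series, "rms_series"))
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  dt <- if (length(series$t) > 1) stats::median(diff(series$t)) else window
  k <- max(1L, round(window / dt))
  rms_series(series$t, moving_average(series$rms, k), window = series$window,
             bead_id = series$bead_id)
}

#' Pointwise ensemble average of RMS series
#'
#' Averages the member series at each time point, using whichever series are
#' present (non-NA) there; the number of contributing series per point is
#' attached as attribute `"count"`. Time stamps are matched after rounding to
#' a microsecond, so series produced on the same acquisition grid align
#' exactly.
#'
#' @param ens An [aligned_ensemble()].
#' @return An [rms_series()] (the ensemble mean).
#' @export
ensemble_average <- function(ens) {
  stopifnot(inherits(ens, "aligned_ensemble"))
  keys <- lapply(ens$series, function(s) round(s$t, 6))
  grid <- sort(unique(unlist(keys)))
  sums <- numeric(length(grid))
  cnt <- integer(length(grid))
  for (i in seq_along(ens$series)) {
    idx <- match(keys[[i]], grid)
    v <- ens$series[[i]]$rms
    ok <- !is.na(v)
    sums[idx[ok]] <- sums[idx[ok]] + v[ok]
    cnt[idx[ok]] <- cnt[idx[ok]] + 1L
  }
  avg <- ifelse(cnt > 0L, sums / cnt, NA_real_)
  out <- rms_series(grid, avg, window = ens$series[[1]]$window,
                    bead_id = paste0("mean(", ens$condition, ")"))
  attr(out, "count") <- cnt
  out
}

#' Fit an exponential collapse to an RMS series
#'
#' Least-squares fit of the decaying exponential
#' \deqn{R(t) = R_\infty + (R_0 - R_\infty)\, e^{-t/\tau}}
#' to a (typically smoothed, ensemble-averaged) RMS series. The time constant
#' is reported in minutes. The fit is flagged unidentifiable -- rather than
#' reporting a meaningless time constant -- when the optimiser fails, the
#' relative standard error of \eqn{\hat\tau} exceeds 50%, \eqn{\hat\tau}
#' exceeds five times the record length, or the fitted amplitude
#' \eqn{R_0 - R_\infty} is not resolved above twice its standard error (the
#' flat-control case). In a flagged fit the reported levels `R0`/`Rinf`
#' revert to model-free head/tail means of the series, since along the
#' unidentifiable directions the exponential's own level parameters are
#' arbitrary.
#'
#' @param series An [rms_series()].
#' @param tau_init Optional initial time constant, minutes.
#' @param zero_offset Force \eqn{R_\infty = 0} (pure exponential decay).
#' @return An object of class `decay_fit`: fields `R0`, `Rinf` (nm),
#'   `tau_min`, `tau_se_min`, `identifiable`, `flag`, `rss`, `resid_sd`, `n`.
#' @export
fit_exponential_decay <- function(series, tau_init = NULL, zero_offset = FALSE) {
  stopifnot(inherits(series, "rms_series"))
  ok <- !is.na(series$rms)
  tt <- series$t[ok]
  r <- series$rms[ok]
  if (length(r) < 10L) stop("need at least 10 points to fit a decay")
  span <- tt[length(tt)] - tt[1]
  n_head <- max(3L, ceiling(0.05 * length(r)))
  n_tail <- max(3L, ceiling(0.10 * length(r)))
  R0s <- mean(r[seq_len(n_head)])
  Rinfs <- if (zero_offset) 0 else mean(r[(length(r) - n_tail + 1L):length(r)])
  tau0 <- if (!is.null(tau_init)) tau_init * 60 else {
    amp <- R0s - Rinfs
    pos <- which(r - Rinfs > 0.05 * abs(amp))
    t0 <- tryCatch({
      cf <- stats::coef(stats::lm(log(r[pos] - Rinfs) ~ tt[pos]))
      as.numeric(-1 / cf[2])
    }, error = function(e) NA_real_)
    if (is.finite(t0) && t0 > 0) t0 else span / 3
  }
  dat <- data.frame(tt = tt, r = r)
  # A time constant below a few times the point spacing (or a tiny fraction
  # of the record) is indistinguishable from a level shift and lets R0 run
  # away; keep the optimiser out of that degenerate basin.
  tau_floor <- max(span * 5e-3, stats::median(diff(tt)))
  tau0 <- max(tau0, 2 * tau_floor)
  fit <- tryCatch({
    if (zero_offset) {
      minpack.lm::nlsLM(r ~ R0 * exp(-tt / tau), data = dat,
                        start = list(R0 = max(R0s, 1e-6), tau = tau0),
                        lower = c(R0 = 0, tau = tau_floor),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(r ~ Rinf + (R0 - Rinf) * exp(-tt / tau), data = dat,
                        start = list(R0 = max(R0s, 1e-6),
                                     Rinf = max(Rinfs, 0), tau = tau0),
                        lower = c(R0 = 0, Rinf = 0, tau = tau_floor),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  flag <- NA_character_
  if (is.null(fit)) {
    out <- list(R0 = R0s, Rinf = Rinfs, tau_min = NA_real_,
                tau_se_min = NA_real_, identifiable = FALSE,
                flag = "fit did not converge", rss = NA_real_,
                resid_sd = NA_real_, n = length(r))
    class(out) <- "decay_fit"
    return(out)
  }
  co <- summary(fit)$coefficients
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  # Dense windowed/smoothed RMS samples are strongly autocorrelated; the
  # nominal least-squares errors assume independence. Inflate them by the
  # AR(1) effective-sample-size factor sqrt((1+rho)/(1-rho)) estimated from
  # the lag-1 autocorrelation of the residuals.
  res <- stats::resid(fit)
  rho_res <- {
    rz <- res - mean(res)
    den <- sum(rz^2)
    if (den <= 0) 0 else max(min(sum(rz[-1] * rz[-length(rz)]) / den, 0.99999), 0)
  }
  infl <- sqrt((1 + rho_res) / (1 - rho_res))
  co[, "Std. Error"] <- co[, "Std. Error"] * infl
  if (!is.null(vc)) vc <- vc * infl^2
  tau <- co["tau", "Estimate"]
  tau_se <- co["tau", "Std. Error"]
  R0 <- co["R0", "Estimate"]
  Rinf <- if (zero_offset) 0 else co["Rinf", "Estimate"]
  amp <- R0 - Rinf
  amp_se <- if (zero_offset) co["R0", "Std. Error"] else if (!is.null(vc)) {
    sqrt(max(vc["R0", "R0"] + vc["Rinf", "Rinf"] - 2 * vc["R0", "Rinf"], 0))
  } else NA_real_
  if (!is.finite(tau_se) || tau_se / tau > 0.5) {
    flag <- "time constant unresolved (relative SE > 50%)"
  } else if (tau > 5 * span) {
    flag <- "time constant exceeds 5x the record length"
  } else if (is.finite(amp_se) && abs(amp) <= 2 * amp_se) {
    flag <- "no significant decay amplitude"
  }
  if (!is.na(flag)) {
    # unidentifiable exponential: the fitted levels can run away along the
    # tau -> infinity (affine ramp) degeneracy; report the model-free
    # head/tail means as the level estimates instead
    R0 <- R0s
    Rinf <- if (zero_offset) 0 else mean(r[(length(r) - n_tail + 1L):length(r)])
  }
  rss <- sum(stats::resid(fit)^2)
  out <- list(R0 = R0, Rinf = Rinf, tau_min = tau / 60,
              tau_se_min = tau_se / 60, identifiable = is.na(flag),
              flag = flag, rss = rss,
              resid_sd = sqrt(rss / max(length(r) - length(co[, 1]), 1)),
              n = length(r))
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$identifiable) {
    cat(sprintf(
      "Exponential collapse: tau = %.2f +/- %.2f min, R0 = %.0f nm -> Rinf = %.0f nm\n",
      x$tau_min, x$tau_se_min, x$R0, x$Rinf))
  } else {
    cat(sprintf("Exponential collapse: UNIDENTIFIABLE (%s)\n", x$flag))
  }
  invisible(x)
}

#' Gaussian fit to the pooled late-time RMS histogram
#'
#' Pools the windowed-RMS samples of every series in the ensemble beyond
#' `from_min` minutes (default 15, by which time a collapsing tether has
#' reached its plateau) and fits a Gaussian by maximum likelihood, i.e. the
#' sample mean and (divide-by-n) standard deviation.
#'
#' @param ens An [aligned_ensemble()].
#' @param from_min Pool samples with t >= `from_min` minutes.
#' @return An object of class `histogram_fit`: `mean`, `sigma` (nm), `n`,
#'   `from_min`, `flag` (`"insufficient samples"` below 30 samples,
#'   `"degenerate"` when all samples coincide).
#' @export
histogram_gaussian_fit <- function(ens, from_min = 15) {
  stopifnot(inherits(ens, "aligned_ensemble"), from_min >= 0)
  pooled <- unlist(lapply(ens$series, function(s) s$rms[s$t >= from_min * 60]))
  pooled <- pooled[!is.na(pooled)]
  flag <- NA_character_
  if (length(pooled) < 30L) flag <- "insufficient samples"
  m <- if (length(pooled)) mean(pooled) else NA_real_
  s <- if (length(pooled)) sqrt(mean((pooled - m)^2)) else NA_real_
  if (is.finite(s) && is.finite(m) && s <= 1e-12 * max(m, 1)) flag <- "degenerate"
  structure(list(mean = m, sigma = s, n = length(pooled),
                 from_min = from_min, condition = ens$condition,
                 flag = flag),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("RMS histogram '%s' (t >= %g min): mean %.1f nm, sigma %.1f nm, n = %d%s\n",
              x$condition, x$from_min, x$mean, x$sigma, x$n,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Compaction ratio of a fitted collapse
#'
#' The ratio of the plateau to the initial RMS excursion,
#' \eqn{R_\infty / R_0}; condensed tethers end up at one half to one third of
#' the pre-stretch excursion (deeper at high protein concentration).
#'
#' For a non-collapsing control the time constant is unidentifiable but the
#' plateau and initial levels still coincide, so the ratio is returned
#' (approximately 1) with a warning; only a fit that failed outright errors.
#'
#' @param fit A converged `decay_fit`.
#' @return Dimensionless ratio in (0, 1] for collapse data.
#' @export
compaction_ratio <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!is.finite(fit$R0) || !is.finite(fit$Rinf) || fit$R0 <= 0) {
    stop("compaction ratio undefined: no usable level estimates")
  }
  if (!isTRUE(fit$identifiable)) {
    warning("decay fit is flagged (", fit$flag,
            "); compaction ratio may be meaningless")
  }
  fit$Rinf / fit$R0
}

#' Saturating-exponential trend of persistence length vs concentration
#'
#' Descriptive interpolation of persistence-length estimates across protein
#' concentrations: \eqn{\xi(c) = \xi_\infty - (\xi_\infty - \xi_0)
#' e^{-c/c_0}} is fitted per condition. Flat data reduce to a constant with
#' the concentration scale flagged unidentifiable.
#'
#' @param data Data frame with columns `concentration_nM`, `xi_nm` and
#'   optionally `condition`.
#' @return A data frame, one row per condition, with columns `condition`,
#'   `xi0`, `xi_inf`, `c0`, `rss`, `n`, `flag`.
#' @export
concentration_trend <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration_nM", "xi_nm") %in% names(data)))
  if (!"condition" %in% names(data)) data$condition <- "all"
  out <- lapply(split(data, data$condition), function(d) {
    d <- d[order(d$concentration_nM), ]
    n <- nrow(d)
    if (n < 3L) stop("need at least 3 concentrations per condition")
    res <- data.frame(condition = d$condition[1], xi0 = NA_real_,
                      xi_inf = NA_real_, c0 = NA_real_, rss = NA_real_,
                      n = n, flag = NA_character_,
                      stringsAsFactors = FALSE)
    if (stats::sd(d$xi_nm) < 1e-9 * max(abs(d$xi_nm), 1)) {
      res$xi0 <- res$xi_inf <- mean(d$xi_nm)
      res$rss <- 0
      res$flag <- "flat data: concentration scale unidentifiable"
      return(res)
    }
    cmax <- max(d$concentration_nM)
    fit <- NULL
    for (c0_start in cmax / c(10, 3, 1.5)) {  # multi-start the scale
      cand <- tryCatch(
        minpack.lm::nlsLM(
          xi_nm ~ xi_inf - (xi_inf - xi0) * exp(-concentration_nM / c0),
          data = d,
          start = list(xi0 = d$xi_nm[1], xi_inf = d$xi_nm[n], c0 = c0_start),
          lower = c(xi0 = 0, xi_inf = 0, c0 = 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2) - 1e-12)) {
        fit <- cand
      }
    }
    if (is.null(fit)) {
      res$xi0 <- res$xi_inf <- mean(d$xi_nm)
      res$flag <- "fit did not converge; constant fallback"
      return(res)
    }
    co <- summary(fit)$coefficients
    res$xi0 <- co["xi0", "Estimate"]
    res$xi_inf <- co["xi_inf", "Estimate"]
    res$c0 <- co["c0", "Estimate"]
    res$rss <- sum(stats::resid(fit)^2)
    if (is.finite(co["c0", "Std. Error"]) &&
        co["c0", "Std. Error"] / res$c0 > 1) {
      res$flag <- "concentration scale poorly identified"
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
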