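#' Force-extension curve of a single tether
#'
#' One optical-tweezers sweep: extension/force pairs, an optional per-point
#' sweep phase (high-to-low force "down", then back "up"), and the
#' acquisition time of the sweep relative to the end of protein incubation.
#'
#' @param z Extensions, nm (>= 0).
#' @param f Forces, pN. Small negative values are admitted: near zero
#'   tension a force transducer reports noise scatter on both sides of
#'   zero, and truncating it would bias downstream fits.
#' @param phase Optional per-point labels (`"down"`/`"up"`).
#' @param timestamp Acquisition time of the sweep, s (NA if unknown).
#' @return An object of class `fe_curve`.
#' @export
fe_curve <- function(z, f, phase = NULL, timestamp = NA_real_) {
  stopifnot(is.numeric(z), is.numeric(f), length(z) == length(f))
  if (length(z) < 5L) stop("a force-extension curve needs at least 5 points")
  if (any(!is.finite(z)) || any(!is.finite(f))) stop("non-finite data")
  if (any(z < 0)) stop("extensions must be non-negative")
  if (!is.null(phase)) {
    stopifnot(length(phase) == length(z))
    phase <- as.character(phase)
  }
  structure(list(z = z, f = f, phase = phase,
                 timestamp = as.numeric(timestamp)[1]),
            class = "fe_curve")
}

#' @export
print.fe_curve <- function(x, ...) {
  cat(sprintf("Force-extension curve: %d points, z in [%.0f, %.0f] nm, f up to %.2f pN%s\n",
              length(x$z), min(x$z), max(x$z), max(x$f),
              if (is.finite(x$timestamp)) sprintf(", t = %g s", x$timestamp) else ""))
  invisible(x)
}

#' Read a force-extension curve from CSV (`z_nm,f_pN[,phase,timestamp_s]`)
#' @param path Input path.
#' @return An [fe_curve()].
#' @export
read_fx_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("z_nm", "f_pN")
  if (!all(need %in% names(df))) {
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  fe_curve(df$z_nm, df$f_pN,
           phase = if ("phase" %in% names(df)) df$phase else NULL,
           timestamp = if ("timestamp_s" %in% names(df)) df$timestamp_s[1] else NA_real_)
}

#' Write a force-extension curve to CSV
#' @param curve An [fe_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fx_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fe_curve"))
  df <- data.frame(z_nm = sprintf("%.17g", curve$z),
                   f_pN = sprintf("%.17g", curve$f))
  if (!is.null(curve$phase)) df$phase <- curve$phase
  if (is.finite(curve$timestamp)) df$timestamp_s <- sprintf("%.17g", curve$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

wlc_fit_result <- function(xi, xi_se, Lc, Lc_se, rss, n, model_tag,
                           converged = TRUE, flag = NA_character_,
                           timestamp = NA_real_) {
  k <- if (model_tag == "free_LC") 2L else 1L
  structure(list(xi = xi, xi_se = xi_se, Lc = Lc, Lc_se = Lc_se, rss = rss,
                 n = n, n_par = k,
                 aic = n * log(max(rss, 1e-300) / n) + 2 * (k + 1),
                 model_tag = model_tag, converged = converged, flag = flag,
                 timestamp = timestamp),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("WLC fit (%s): xi = %.2f +/- %.2f nm", x$model_tag, x$xi, x$xi_se))
  if (x$model_tag == "free_LC") {
    cat(sprintf(", L_C = %.1f +/- %.1f nm", x$Lc, x$Lc_se))
  } else {
    cat(sprintf(", L_C fixed at %.1f nm", x$Lc))
  }
  cat(sprintf("  (RSS %.4g, n = %d%s)\n", x$rss, x$n,
              if (!x$converged) ", NOT CONVERGED"
              else if (!is.na(x$flag)) paste0(", ", x$flag) else ""))
  invisible(x)
}

#' Fit the Marko-Siggia WLC with fixed contour length
#'
#' Least-squares estimate of the persistence length \eqn{\xi} from a
#' force-extension curve at a known contour length, minimising the vertical
#' (force) residuals \eqn{\sum_i (f_i - f_{WLC}(z_i; \xi, L_C))^2}. At fixed
#' \eqn{L_C} the Marko-Siggia law is linear in \eqn{1/\xi}, so the optimum is
#' a regression through the origin of \eqn{f} on
#' \eqn{k_BT\,g(z/L_C)}; the standard error of \eqn{\hat\xi} follows from the
#' regression slope error by the delta method.
#'
#' @param curve An [fe_curve()].
#' @param contour_length Fixed contour length, nm; all `z` must lie below it.
#' @param kBT Thermal energy, pN nm.
#' @return A `wlc_fit` with `model_tag = "fixed_LC"`.
#' @export
fit_wlc_fixed_lc <- function(curve, contour_length, kBT = 4.1) {
  stopifnot(inherits(curve, "fe_curve"), contour_length > 0, kBT > 0)
  if (any(curve$z >= contour_length)) {
    stop("extension(s) at or beyond the fixed contour length")
  }
  x <- kBT * wlc_g(curve$z / contour_length)
  n <- length(x)
  sxx <- sum(x^2)
  beta <- sum(x * curve$f) / sxx
  rss <- sum((curve$f - beta * x)^2)
  if (beta <= 0) {
    return(wlc_fit_result(NA_real_, NA_real_, contour_length, NA_real_, rss,
                          n, "fixed_LC", converged = FALSE,
                          flag = "non-positive slope",
                          timestamp = curve$timestamp))
  }
  se_beta <- sqrt(rss / (n - 1) / sxx)
  wlc_fit_result(xi = 1 / beta, xi_se = se_beta / beta^2,
                 Lc = contour_length, Lc_se = NA_real_, rss = rss, n = n,
                 model_tag = "fixed_LC", timestamp = curve$timestamp)
}

#' Fit the Marko-Siggia WLC with free contour length
#'
#' Joint least squares over \eqn{(\xi, L_C)} with the contour length bounded
#' below by \eqn{\max(z)\,(1+10^{-3})} (the force law is undefined at
#' \eqn{z \ge L_C}). To avoid the local minimum at the boundary, the
#' optimiser is multi-started from `start_factors * max(z)` (plus `Lc_init`
#' when supplied) and the lowest-RSS converged solution is kept. A fit whose
#' contour length lands on the lower bound is flagged `"boundary"`.
#'
#' @param curve An [fe_curve()] with at least 6 points.
#' @param kBT Thermal energy, pN nm.
#' @param Lc_init Optional initial contour length, nm (> max(z)).
#' @param start_factors Multipliers of `max(z)` used as contour-length
#'   starting points.
#' @return A `wlc_fit` with `model_tag = "free_LC"`.
#' @export
fit_wlc_free_lc <- function(curve, kBT = 4.1, Lc_init = NULL,
                            start_factors = c(1.05, 1.2, 1.5)) {
  stopifnot(inherits(curve, "fe_curve"), kBT > 0)
  if (length(curve$z) < 6L) stop("free-contour fit needs at least 6 points")
  zmax <- max(curve$z)
  bound <- zmax * (1 + 1e-3)
  starts <- unique(c(Lc_init, start_factors * zmax))
  starts <- starts[starts > bound]
  if (length(starts) == 0) stop("Lc_init must exceed max(z)")
  dat <- data.frame(z = curve$z, f = curve$f)
  best <- NULL
  for (Lc0 in starts) {
    xi0 <- tryCatch(
      fit_wlc_fixed_lc(curve, Lc0, kBT)$xi,
      error = function(e) NA_real_)
    if (!is.finite(xi0) || xi0 <= 0) xi0 <- 50
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ (kBT / xi) * (1 / (4 * (1 - z / Lc)^2) - 0.25 + z / Lc),
        data = dat, start = list(xi = xi0, Lc = Lc0),
        lower = c(xi = 1e-2, Lc = bound),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(wlc_fit_result(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                          length(curve$z), "free_LC", converged = FALSE,
                          flag = "no converged start",
                          timestamp = curve$timestamp))
  }
  co <- summary(best$fit)$coefficients
  Lc_hat <- co["Lc", "Estimate"]
  flag <- if (Lc_hat <= bound * (1 + 1e-6)) "boundary" else NA_character_
  wlc_fit_result(xi = co["xi", "Estimate"], xi_se = co["xi", "Std. Error"],
                 Lc = Lc_hat, Lc_se = co["Lc", "Std. Error"],
                 rss = best$rss, n = length(curve$z), model_tag = "free_LC",
                 converged = is.na(flag), flag = flag,
                 timestamp = curve$timestamp)
}

#' Nested-model comparison: is a free contour length warranted?
#'
#' Compares the fixed-\eqn{L_C} and free-\eqn{L_C} WLC fits of the same curve
#' with the nested-model F-test (one extra parameter):
#' \deqn{F = \frac{RSS_{fixed} - RSS_{free}}{RSS_{free}/(n-2)},}
#' referred to \eqn{F_{1, n-2}}. AIC values are reported alongside. When both
#' residual sums are numerically zero (noiseless data) the comparison is
#' flagged degenerate instead of dividing by zero.
#'
#' @param curve An [fe_curve()].
#' @param contour_length The fixed (expected) contour length, nm.
#' @param kBT Thermal energy, pN nm.
#' @param alpha Significance level for preferring the free model.
#' @return An object of class `model_comparison` with `rss_fixed`,
#'   `rss_free`, `F_statistic`, `p_value`, `preferred_model`, `aic_fixed`,
#'   `aic_free`, `degenerate`, and both fits.
#' @export
compare_models <- function(curve, contour_length, kBT = 4.1, alpha = 0.05) {
  fit_fixed <- fit_wlc_fixed_lc(curve, contour_length, kBT)
  fit_free <- fit_wlc_free_lc(curve, kBT, Lc_init = if (contour_length > max(curve$z) * (1 + 1e-3)) contour_length else NULL)
  if (!fit_fixed$converged || is.na(fit_free$rss)) {
    stop("model comparison requires both fits to converge")
  }
  rss_fixed <- fit_fixed$rss
  rss_free <- min(fit_free$rss, rss_fixed)  # free model nests the fixed one
  n <- fit_fixed$n
  scale <- max(mean(curve$f^2), 1e-30)
  degenerate <- rss_free < 1e-12 * n * scale
  if (degenerate) {
    Fstat <- 0
    p <- NA_real_
    preferred <- "fixed_LC"
  } else {
    Fstat <- max(0, (rss_fixed - rss_free)) / (rss_free / (n - 2))
    p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
    preferred <- if (p < alpha) "free_LC" else "fixed_LC"
  }
  structure(list(rss_fixed = rss_fixed, rss_free = rss_free,
                 F_statistic = Fstat, p_value = p,
                 preferred_model = preferred, alpha = alpha,
                 aic_fixed = fit_fixed$aic, aic_free = fit_free$aic,
                 degenerate = degenerate,
                 fit_fixed = fit_fixed, fit_free = fit_free),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Nested WLC model comparison (alpha = %g):\n", x$alpha))
  cat(sprintf("  RSS fixed L_C: %.4g   RSS free L_C: %.4g\n",
              x$rss_fixed, x$rss_free))
  if (x$degenerate) {
    cat("  degenerate (zero residuals); defaulting to the fixed-L_C model\n")
  } else {
    cat(sprintf("  F = %.3g, p = %.3g -> preferred: %s\n",
                x$F_statistic, x$p_value, x$preferred_model))
  }
  invisible(x)
}

#' Relative contour length over time from a series of free-contour fits
#'
#' Expresses each fitted contour length relative to the earliest fit,
#' reproducing the "relative change in contour length" view of a condensing
#' tether whose force-extension curves shift to lower extension over time.
#'
#' @param fits List of `wlc_fit` objects from [fit_wlc_free_lc()], each with
#'   a finite `timestamp`.
#' @return A data frame (`timestamp_s`, `Lc_nm`, `relative_Lc`) ordered by
#'   time, with attribute `"monotone_decreasing"` reporting whether the
#'   ratios only ever decrease.
#' @export
relative_contour_series <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  ok <- vapply(fits, function(f) inherits(f, "wlc_fit") &&
                 is.finite(f$timestamp) && is.finite(f$Lc), logical(1))
  if (!all(ok)) stop("all fits must be wlc_fit objects with finite timestamps and contour lengths")
  ts <- vapply(fits, `[[`, numeric(1), "timestamp")
  Lc <- vapply(fits, `[[`, numeric(1), "Lc")
  o <- order(ts)
  out <- data.frame(timestamp_s = ts[o], Lc_nm = Lc[o],
                    relative_Lc = Lc[o] / Lc[o][1])
  attr(out, "monotone_decreasing") <- all(diff(out$relative_Lc) <= 1e-9)
  out
}
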