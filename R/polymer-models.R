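#' Tether model: polymer and bead geometry of a single DNA tether
#'
#' Bundles the parameters that determine the mechanics of a surface-tethered
#' DNA-bead construct: the DNA contour length \eqn{L_C} and persistence length
#' \eqn{\xi}, the thermal energy \eqn{k_B T}, and the radius \eqn{R} of the
#' reporter microsphere. All lengths are in nm, energies in pN nm, so forces
#' come out in pN.
#'
#' The dimensionless excursion number
#' \eqn{N_R = R / \sqrt{L_C \xi / 3}} compares the bead radius to the scale of
#' the tether's equilibrium fluctuations; it controls the bead-size correction
#' in the Gaussian-chain excursion formula (see [rms_from_persistence()]).
#'
#' @param contour_length Contour length \eqn{L_C} in nm; must be positive.
#' @param persistence_length Persistence length \eqn{\xi} in nm; must be
#'   positive. Bare B-DNA is roughly 50 nm.
#' @param kBT Thermal energy in pN nm. Default 4.1 (room temperature).
#' @param bead_radius Microsphere radius \eqn{R} in nm; zero means a point
#'   marker at the DNA end.
#' @return An object of class `tether_model`.
#' @examples
#' m <- tether_model(contour_length_from_bp(5092), 54, bead_radius = 500)
#' rms_from_persistence(m)
#' @export
tether_model <- function(contour_length, persistence_length, kBT = 4.1,
                         bead_radius = 0) {
  stopifnot(is.numeric(contour_length), length(contour_length) == 1L,
            is.finite(contour_length), contour_length > 0,
            is.numeric(persistence_length), length(persistence_length) == 1L,
            is.finite(persistence_length), persistence_length > 0,
            is.numeric(kBT), length(kBT) == 1L, is.finite(kBT), kBT > 0,
            is.numeric(bead_radius), length(bead_radius) == 1L,
            is.finite(bead_radius), bead_radius >= 0)
  structure(
    list(contour_length = contour_length,
         persistence_length = persistence_length,
         kBT = kBT,
         bead_radius = bead_radius),
    class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat("Tether model:\n")
  cat(sprintf("  contour length     L_C = %.1f nm\n", x$contour_length))
  cat(sprintf("  persistence length xi  = %.1f nm\n", x$persistence_length))
  cat(sprintf("  thermal energy     kBT = %.2f pN nm\n", x$kBT))
  cat(sprintf("  bead radius        R   = %.1f nm (N_R = %.2f)\n",
              x$bead_radius, excursion_number(x)))
  invisible(x)
}

#' Excursion number of a tether model
#'
#' \eqn{N_R = R / \sqrt{L_C \xi / 3}}, the bead radius in units of the
#' tether's fluctuation scale.
#'
#' @param model A [tether_model()].
#' @return Dimensionless excursion number (>= 0).
#' @export
excursion_number <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  model$bead_radius / sqrt(model$contour_length * model$persistence_length / 3)
}

#' Contour length of B-DNA from a base-pair count
#'
#' Multiplies the number of base pairs by the helical rise per base pair
#' (canonical B-DNA: 0.34 nm/bp). A 5092 bp fragment is about 1.7 um.
#'
#' @param n_bp Number of base pairs (> 0).
#' @param rise_per_bp Rise per base pair in nm (> 0). Default 0.34.
#' @return Contour length in nm.
#' @examples
#' contour_length_from_bp(5092)  # ~1731 nm
#' @export
contour_length_from_bp <- function(n_bp, rise_per_bp = 0.34) {
  stopifnot(is.numeric(n_bp), all(is.finite(n_bp)), all(n_bp > 0),
            is.numeric(rise_per_bp), length(rise_per_bp) == 1L,
            is.finite(rise_per_bp), rise_per_bp > 0)
  n_bp * rise_per_bp
}

# Marko-Siggia bracket as a function of fractional extension u = z/L_C
wlc_g <- function(u) 1 / (4 * (1 - u)^2) - 0.25 + u

#' Marko-Siggia worm-like-chain force law
#'
#' Entropic restoring force of a worm-like chain at extension \eqn{z}:
#' \deqn{f(z) = \frac{k_B T}{\xi}\left(\frac{1}{4(1-z/L_C)^2} - \frac14 +
#'   \frac{z}{L_C}\right).}
#' The force vanishes at \eqn{z = 0}, is strictly increasing, reduces to the
#' Hookean law \eqn{3 k_B T z / (2 \xi L_C)} at small extension, and diverges
#' as \eqn{z \to L_C}.
#'
#' @param z Extension(s) in nm; must satisfy \eqn{0 \le z < L_C}.
#' @param model A [tether_model()].
#' @return Force(s) in pN.
#' @examples
#' m <- tether_model(1731.3, 53)
#' wlc_force(0.85 * 1731.3, m)  # ~0.906 pN
#' @export
wlc_force <- function(z, model) {
  stopifnot(inherits(model, "tether_model"), is.numeric(z), all(is.finite(z)))
  if (any(z < 0)) stop("extension must be non-negative")
  if (any(z >= model$contour_length)) {
    stop("extension must be below the contour length (the WLC force diverges at z = L_C)")
  }
  (model$kBT / model$persistence_length) * wlc_g(z / model$contour_length)
}

#' Extension of a worm-like chain at a given force
#'
#' Numeric inverse of [wlc_force()]: the unique extension
#' \eqn{z \in [0, L_C)} at which the Marko-Siggia force equals `force`.
#' Bracketed root-finding on the strictly increasing force law guarantees
#' convergence.
#'
#' @param force Force(s) in pN, each >= 0.
#' @param model A [tether_model()].
#' @param tol Absolute tolerance on the returned extension, nm.
#' @return Extension(s) in nm.
#' @export
wlc_extension <- function(force, model, tol = 1e-6) {
  stopifnot(inherits(model, "tether_model"), is.numeric(force),
            all(is.finite(force)))
  if (any(force < 0)) stop("force must be non-negative")
  Lc <- model$contour_length
  vapply(force, function(f) {
    if (f == 0) return(0)
    eps <- 0.25
    while (wlc_force(Lc * (1 - eps), model) < f && eps > 1e-12) eps <- eps / 2
    stats::uniroot(function(z) wlc_force(z, model) - f,
                   lower = 0, upper = Lc * (1 - eps), tol = tol)$root
  }, numeric(1))
}

# Gaussian-chain in-plane RMS excursion of the bead centre (closed form)
eq_rms <- function(Lc, xi, R) {
  s2 <- Lc * xi / 3
  N <- R / sqrt(s2)
  # 4N / (sqrt(pi) erf(N)) -> 2 as N -> 0
  bracket <- if (N < 1e-6) 4 else 2 + 4 * N / (sqrt(pi) * erf(N))
  sqrt(s2 * bracket)
}

#' Predicted in-plane RMS bead excursion of a tethered bead
#'
#' Gaussian-chain prediction for the root-mean-square in-plane excursion of
#' the centre of a bead of radius \eqn{R} tethered by DNA of contour length
#' \eqn{L_C} and persistence length \eqn{\xi} above a surface:
#' \deqn{R_{RMS} = \sqrt{\frac{L_C \xi}{3}\left(2 +
#'   \frac{4 N_R}{\sqrt{\pi}\,\mathrm{erf}(N_R)}\right)},}
#' with excursion number \eqn{N_R = R/\sqrt{L_C \xi/3}}. For a point marker
#' (\eqn{R = 0}) the bracket reduces to 4, i.e.
#' \eqn{R_{RMS} = 2\sqrt{L_C\xi/3}}, the free-chain in-plane value.
#'
#' @param model A [tether_model()].
#' @return RMS excursion in nm.
#' @examples
#' rms_from_persistence(tether_model(1731.3, 54, bead_radius = 500))  # ~508 nm
#' @export
rms_from_persistence <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  eq_rms(model$contour_length, model$persistence_length, model$bead_radius)
}

#' Persistence length from an observed RMS bead excursion
#'
#' Inverts the Gaussian-chain excursion formula (see
#' [rms_from_persistence()]) for the persistence length \eqn{\xi} given the
#' measured in-plane RMS excursion, the DNA contour length and the bead
#' radius. The map \eqn{\xi \mapsto R_{RMS}} is strictly increasing, so a
#' bracketed root search on `interval` converges to the unique solution.
#'
#' @param r_rms Observed in-plane RMS excursion, nm (> 0).
#' @param contour_length DNA contour length, nm.
#' @param bead_radius Bead radius, nm.
#' @param interval Search bracket for \eqn{\xi}, nm.
#' @param tol Absolute tolerance on \eqn{\xi}, nm.
#' @return Persistence length in nm.
#' @examples
#' persistence_from_rms(508, contour_length_from_bp(5092), bead_radius = 500)
#' @export
persistence_from_rms <- function(r_rms, contour_length, bead_radius = 0,
                                 interval = c(0.1, 1000), tol = 1e-4) {
  stopifnot(is.numeric(r_rms), length(r_rms) == 1L, is.finite(r_rms),
            r_rms > 0, contour_length > 0, bead_radius >= 0,
            length(interval) == 2L, interval[1] > 0, interval[2] > interval[1])
  lo <- eq_rms(contour_length, interval[1], bead_radius)
  hi <- eq_rms(contour_length, interval[2], bead_radius)
  if (r_rms < lo || r_rms > hi) {
    stop(sprintf(paste0(
      "r_rms = %.3g nm is outside the attainable range [%.3g, %.3g] nm for ",
      "xi in [%.3g, %.3g] nm at L_C = %.4g nm, R = %.4g nm"),
      r_rms, lo, hi, interval[1], interval[2], contour_length, bead_radius))
  }
  stats::uniroot(function(xi) eq_rms(contour_length, xi, bead_radius) - r_rms,
                 lower = interval[1], upper = interval[2], tol = tol)$root
}
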