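#' Configuration for the tethered-bead trajectory simulator
#'
#' Describes a synthetic TPM acquisition. Each in-plane axis is simulated as
#' a mean-reverting (Ornstein-Uhlenbeck) Gaussian process with positional
#' correlation time `tau_c`, whose stationary per-axis standard deviation is
#' \eqn{\sigma_{ax}(t) = R_{RMS}(t)/\sqrt 2}. Before any collapse,
#' \eqn{R_{RMS}} is the Gaussian-chain prediction for `model` (or `rms0` when
#' given); with a `collapse` the amplitude relaxes exponentially (time
#' constant `tau_min` minutes) from its initial value to
#' `plateau_fraction * R_RMS` after `start_time`. Slow stage drift, a
#' discrete stuck-bead amplitude drop, and per-axis anisotropy (screening
#' fixtures) can be superimposed. The seed fixes the whole output stream.
#'
#' @param model A [tether_model()] (optional when `rms0` is given).
#' @param rms0 Initial in-plane RMS excursion, nm; overrides the model
#'   prediction.
#' @param sample_rate Camera rate, Hz (default 25).
#' @param duration Record length, s.
#' @param tau_c Positional correlation time, s (default 0.1).
#' @param drift `list(amplitude = nm, type = "linear"|"random_walk")` or NULL.
#' @param collapse `list(tau_min, plateau_fraction, start_time = 0)` or NULL.
#' @param stuck `list(time = s, residual_fraction)` or NULL.
#' @param anisotropy Length-2 per-axis scale factors (x, y).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return An object of class `tpm_sim_config`.
#' @export
tpm_sim_config <- function(model = NULL, rms0 = NULL, sample_rate = 25,
                           duration = 600, tau_c = 0.1, drift = NULL,
                           collapse = NULL, stuck = NULL,
                           anisotropy = c(1, 1), seed = NULL) {
  if (is.null(model) && is.null(rms0)) stop("supply a tether model or rms0")
  if (!is.null(model)) stopifnot(inherits(model, "tether_model"))
  stopifnot(sample_rate > 0, duration > 0, tau_c > 0,
            length(anisotropy) == 2L, all(anisotropy > 0))
  if (!is.null(rms0)) stopifnot(rms0 >= 0)
  if (!is.null(collapse)) {
    stopifnot(is.list(collapse), collapse$tau_min > 0,
              collapse$plateau_fraction > 0, collapse$plateau_fraction <= 1)
    collapse$start_time <- collapse$start_time %||% 0
    stopifnot(collapse$start_time >= 0)
  }
  if (!is.null(stuck)) {
    stopifnot(is.list(stuck), stuck$time >= 0,
              stuck$residual_fraction > 0, stuck$residual_fraction < 1)
  }
  if (!is.null(drift)) {
    stopifnot(is.list(drift), drift$amplitude >= 0,
              drift$type %in% c("linear", "random_walk"))
  }
  structure(list(model = model, rms0 = rms0, sample_rate = sample_rate,
                 duration = duration, tau_c = tau_c, drift = drift,
                 collapse = collapse, stuck = stuck,
                 anisotropy = anisotropy, seed = seed),
            class = "tpm_sim_config")
}

# stationary unit-variance AR(1) path of length n with lag-1 coefficient rho
ar1_path <- function(n, rho) {
  innov <- stats::rnorm(n, sd = sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate a tethered-bead TPM trajectory
#'
#' Generates the in-plane bead positions described by a [tpm_sim_config()].
#' The long-run in-plane RMS of a stationary, drift-free trajectory matches
#' the Gaussian-chain prediction of its tether model by construction.
#'
#' @param config A [tpm_sim_config()].
#' @param bead_id Identifier for the generated trajectory.
#' @return A [tpm_trajectory()]; the configuration is attached as attribute
#'   `"config"`.
#' @export
simulate_tpm <- function(config, bead_id = "sim") {
  stopifnot(inherits(config, "tpm_sim_config"))
  with_seed(config$seed, {
    rate <- config$sample_rate
    n <- max(2L, round(config$duration * rate))
    t <- seq(0, by = 1 / rate, length.out = n)
    rms0 <- config$rms0 %||% rms_from_persistence(config$model)
    amp <- rep(rms0, n)
    if (!is.null(config$collapse)) {
      cl <- config$collapse
      late <- t >= cl$start_time
      amp[late] <- rms0 * (cl$plateau_fraction + (1 - cl$plateau_fraction) *
                             exp(-(t[late] - cl$start_time) / (cl$tau_min * 60)))
    }
    if (!is.null(config$stuck)) {
      amp[t >= config$stuck$time] <- amp[t >= config$stuck$time] *
        config$stuck$residual_fraction
    }
    rho <- exp(-1 / (rate * config$tau_c))
    sig <- amp / sqrt(2)
    x <- sig * config$anisotropy[1] * ar1_path(n, rho)
    y <- sig * config$anisotropy[2] * ar1_path(n, rho)
    if (!is.null(config$drift)) {
      A <- config$drift$amplitude
      if (config$drift$type == "linear") {
        theta <- stats::runif(1, 0, 2 * pi)
        ramp <- A * (t - t[1]) / (t[n] - t[1])
        x <- x + ramp * cos(theta)
        y <- y + ramp * sin(theta)
      } else {
        x <- x + cumsum(stats::rnorm(n, sd = A / sqrt(n)))
        y <- y + cumsum(stats::rnorm(n, sd = A / sqrt(n)))
      }
    }
    out <- tpm_trajectory(t, x, y, bead_id = bead_id)
    attr(out, "config") <- config
    out
  })
}

#' Configuration for the force-extension sweep simulator
#'
#' Describes synthetic optical-tweezers sweeps: the tether model, the
#' fractional extension grid, additive Gaussian force noise, and optionally
#' a contour-length shrink schedule emulating a condensing tether measured
#' repeatedly (curves marching to lower extension). The default grid spans
#' 0.10-0.95 of the contour length; near its top the Marko-Siggia force at
#' a ~53 nm persistence length reaches several pN, matching sweeps taken up
#' to the ~10 pN range.
#'
#' With `grid_mode = "relative"` (default) the fractions apply to the
#' current contour length of each scheduled curve, like an operator
#' rescaling the sweep to the shrinking tether; with `"absolute"` the grid
#' is fixed in nm from the initial contour length and must stay below every
#' scheduled contour length.
#'
#' @param model A [tether_model()].
#' @param grid Strictly increasing extension fractions in (0, 1).
#' @param noise_sd Gaussian force noise, pN (>= 0).
#' @param shrink_schedule Optional data frame `t_s`, `Lc_nm`.
#' @param grid_mode `"relative"` or `"absolute"`.
#' @param two_phase Emit a down (high-to-low force) then up sweep, doubling
#'   the points; otherwise a single down sweep.
#' @param seed Integer seed, or NULL.
#' @return An object of class `fx_sim_config`.
#' @export
fx_sim_config <- function(model, grid = seq(0.10, 0.95, length.out = 30),
                          noise_sd = 0, shrink_schedule = NULL,
                          grid_mode = c("relative", "absolute"),
                          two_phase = FALSE, seed = NULL) {
  stopifnot(inherits(model, "tether_model"), is.numeric(grid),
            length(grid) >= 5L, all(diff(grid) > 0), min(grid) > 0,
            max(grid) < 1, noise_sd >= 0)
  grid_mode <- match.arg(grid_mode)
  if (!is.null(shrink_schedule)) {
    stopifnot(is.data.frame(shrink_schedule),
              all(c("t_s", "Lc_nm") %in% names(shrink_schedule)),
              all(shrink_schedule$Lc_nm > 0))
    if (grid_mode == "absolute" &&
        max(grid) * model$contour_length >= min(shrink_schedule$Lc_nm)) {
      stop("absolute extension grid exceeds the smallest scheduled contour length")
    }
  }
  structure(list(model = model, grid = grid, noise_sd = noise_sd,
                 shrink_schedule = shrink_schedule, grid_mode = grid_mode,
                 two_phase = two_phase, seed = seed),
            class = "fx_sim_config")
}

#' Simulate force-extension sweeps
#'
#' Evaluates the Marko-Siggia force law on the configured extension grid and
#' adds Gaussian force noise. Without a shrink schedule a single [fe_curve()]
#' is returned; with one, a list of curves, one per scheduled time at its
#' scheduled contour length.
#'
#' @param config An [fx_sim_config()].
#' @return An [fe_curve()] or a list of them.
#' @export
simulate_fx <- function(config) {
  stopifnot(inherits(config, "fx_sim_config"))
  with_seed(config$seed, {
    sched <- config$shrink_schedule %||%
      data.frame(t_s = 0, Lc_nm = config$model$contour_length)
    curves <- lapply(seq_len(nrow(sched)), function(i) {
      Lc <- sched$Lc_nm[i]
      m <- tether_model(Lc, config$model$persistence_length,
                        kBT = config$model$kBT,
                        bead_radius = config$model$bead_radius)
      z <- if (config$grid_mode == "relative") config$grid * Lc
           else config$grid * config$model$contour_length
      z <- rev(z)  # down sweep: high force to low force
      phase <- rep("down", length(z))
      if (config$two_phase) {
        z <- c(z, rev(z))
        phase <- c(phase, rep("up", length(z) / 2))
      }
      f <- wlc_force(z, m) + stats::rnorm(length(z), sd = config$noise_sd)
      fe_curve(z, f, phase = phase, timestamp = sched$t_s[i])
    })
    if (is.null(config$shrink_schedule)) curves[[1]] else curves
  })
}

#' Write the canonical synthetic fixture suite
#'
#' Generates, deterministically from `seed`, the full set of synthetic
#' experiments the analysis consumes: an unstretched control ensemble, two
#' collapsing ensembles (100 nM-like, tau = 7.5 min to a 0.4 plateau;
#' 200 nM-like, tau = 7.3 min to a 0.15 plateau), a no-collapse
#' mutant-cofactor ensemble, a shrinking-contour force-extension sweep
#' sequence, and anisotropic / stuck-bead screening cases, together with a
#' JSON manifest recording every ground-truth parameter.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param duration Trajectory length, s (default 1800, a 30 min record).
#' @param n_collapse Trajectories per collapsing ensemble.
#' @param n_control Trajectories per control/mutant ensemble.
#' @return The manifest (a list), invisibly; written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, duration = 1800,
                               n_collapse = 8, n_control = 4) {
  if (!is.character(out_dir) || length(out_dir) != 1L || !nzchar(out_dir)) {
    stop("out_dir must be a non-empty directory path")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- tether_model(contour_length_from_bp(5092), 54, bead_radius = 500)
  sub <- function(k) as.integer(seed * 1000L + k)
  k <- 0L
  sim_set <- function(name, n, collapse = NULL, anisotropy = c(1, 1),
                      stuck = NULL) {
    files <- character(n)
    for (i in seq_len(n)) {
      k <<- k + 1L
      cfg <- tpm_sim_config(model = model, duration = duration,
                            collapse = collapse, anisotropy = anisotropy,
                            stuck = stuck, seed = sub(k))
      traj <- simulate_tpm(cfg, bead_id = sprintf("%s_%02d", name, i))
      files[i] <- sprintf("%s_%02d.csv", name, i)
      write_trajectory(traj, file.path(out_dir, files[i]))
    }
    files
  }
  manifest <- list(
    seed = seed,
    model = list(contour_length_nm = model$contour_length,
                 persistence_length_nm = model$persistence_length,
                 kBT_pN_nm = model$kBT, bead_radius_nm = model$bead_radius),
    rms0_nm = rms_from_persistence(model),
    sample_rate_hz = 25, duration_s = duration,
    ensembles = list(
      control = list(files = sim_set("control", n_control),
                     control = TRUE, concentration_nM = 100),
      hha_hns_100nM = list(
        files = sim_set("hha_hns_100nM", n_collapse,
                        collapse = list(tau_min = 7.5, plateau_fraction = 0.4)),
        control = FALSE, concentration_nM = 100,
        tau_min = 7.5, plateau_fraction = 0.4),
      hha_hns_200nM = list(
        files = sim_set("hha_hns_200nM", n_collapse,
                        collapse = list(tau_min = 7.3, plateau_fraction = 0.15)),
        control = FALSE, concentration_nM = 200,
        tau_min = 7.3, plateau_fraction = 0.15),
      mutant_200nM = list(files = sim_set("mutant_200nM", n_control),
                          control = FALSE, concentration_nM = 200,
                          collapses = FALSE)),
    screening = list(
      anisotropic = list(files = sim_set("anisotropic", 1,
                                         anisotropy = c(1.2, 1)),
                         anisotropy = c(1.2, 1)),
      stuck = list(files = sim_set("stuck", 1,
                                   stuck = list(time = round(duration / 3),
                                                residual_fraction = 0.2)),
                   stuck_time_s = round(duration / 3),
                   residual_fraction = 0.2)))
  k <- k + 1L
  sched <- data.frame(t_s = c(60, 120, 240, 360),
                      Lc_nm = model$contour_length * c(1, 0.9, 0.75, 0.61))
  fx_cfg <- fx_sim_config(model, noise_sd = 0.1, shrink_schedule = sched,
                          seed = sub(k))
  curves <- simulate_fx(fx_cfg)
  fx_files <- sprintf("fx_shrink_%02d.csv", seq_along(curves))
  for (i in seq_along(curves)) {
    write_fx_curve(curves[[i]], file.path(out_dir, fx_files[i]))
  }
  manifest$force_extension <- list(
    files = fx_files, noise_sd_pN = 0.1,
    schedule = list(t_s = sched$t_s, Lc_nm = sched$Lc_nm),
    relative_Lc = sched$Lc_nm / sched$Lc_nm[1])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
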