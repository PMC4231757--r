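# Shared fixtures and independent oracles for the test suite.

# the bare-DNA construct used throughout: 5092 bp tether, 1 um bead
base_model <- function(xi = 54) {
  tether_model(contour_length_from_bp(5092), xi, bead_radius = 500)
}

# simulate one release-aligned collapsing (or control) ensemble and return
# the smoothed member series
sim_ensemble_series <- function(seed, tau_min = NULL, plateau = NULL, n = 8,
                                duration = 1800, rms0 = 500, smooth = 60) {
  m <- base_model()
  collapse <- if (!is.null(tau_min)) {
    list(tau_min = tau_min, plateau_fraction = plateau)
  }
  lapply(seq_len(n), function(i) {
    cfg <- tpm_sim_config(model = m, rms0 = rms0, duration = duration,
                          collapse = collapse, seed = seed * 1000L + i)
    smooth_running_window(windowed_rms(simulate_tpm(cfg), 4), smooth)
  })
}

# Independent Monte-Carlo oracle for the bead-excursion formula: a
# freely-jointed chain of Kuhn length 2*xi (total length Lc) anchored to a
# surface, a bead of radius R attached at the free end with its centre on
# the upper hemisphere, rejecting configurations that penetrate the surface.
# Returns the in-plane RMS of accepted bead centres.
fjc_bead_rms_mc <- function(Lc, xi, R, n_accept = 1e5, seed = 1,
                            batch = 200000L) {
  set.seed(seed)
  b <- 2 * xi
  N <- max(1L, round(Lc / b))
  b <- Lc / N
  tot <- 0
  ss <- 0
  while (tot < n_accept) {
    xe <- numeric(batch); ye <- numeric(batch)
    ze <- numeric(batch); zmin <- numeric(batch)
    for (k in seq_len(N)) {
      cz <- 2 * runif(batch) - 1
      phi <- 2 * pi * runif(batch)
      st <- sqrt(1 - cz^2)
      xe <- xe + b * st * cos(phi)
      ye <- ye + b * st * sin(phi)
      ze <- ze + b * cz
      zmin <- pmin(zmin, ze)
    }
    vz <- runif(batch)  # bead direction uniform on the upper hemisphere
    vphi <- 2 * pi * runif(batch)
    vs <- sqrt(1 - vz^2)
    ok <- zmin >= 0 & (ze + R * vz) >= R
    ss <- ss + sum((xe + R * vs * cos(vphi))[ok]^2 +
                     (ye + R * vs * sin(vphi))[ok]^2)
    tot <- tot + sum(ok)
  }
  sqrt(ss / tot)
}
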