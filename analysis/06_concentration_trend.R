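#!/usr/bin/env Rscript
# Persistence length versus protein concentration, measured three ways as in
# the stiffening assay: pre-stretch TPM, post-stretch TPM and tweezers
# force-extension. Synthetic ground truth: H-NS filaments stiffen DNA with
# saturating concentration dependence; the applied stretch softens the
# filament so post-stretch TPM and tweezers agree below the pre-stretch
# values. Each point is estimated through the full pipeline, then the
# saturating-exponential interpolation is fitted per condition.

library(tpmkit)

dir.create("results", showWarnings = FALSE)
lc <- contour_length_from_bp(5092)
conc <- c(0, 50, 100, 200, 400)

# ground-truth stiffening curves (nm): bare DNA at 54 nm anchors c = 0
xi_true <- list(
  pre_stretch_tpm = 200 - (200 - 54) * exp(-conc / 150),
  post_stretch_tpm = 100 - (100 - 54) * exp(-conc / 150),
  force_extension = 100 - (100 - 54) * exp(-conc / 150))

rows <- list()
for (cond in names(xi_true)) {
  for (i in seq_along(conc)) {
    xi_c <- xi_true[[cond]][i]
    if (cond == "force_extension") {
      curve <- simulate_fx(fx_sim_config(tether_model(lc, xi_c),
                                         noise_sd = 0.2,
                                         seed = 600 + 10 * i))
      est <- fit_wlc_fixed_lc(curve, contour_length = lc)$xi
    } else {
      cfg <- tpm_sim_config(model = tether_model(lc, xi_c, bead_radius = 500),
                            duration = 600,
                            seed = 700 + 10 * i + match(cond, names(xi_true)))
      filt <- drift_filter(simulate_tpm(cfg))
      est <- persistence_from_trajectory(filt, lc, bead_radius = 500)$xi
    }
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, concentration_nM = conc[i],
      xi_true_nm = round(xi_c, 1), xi_nm = round(est, 1))
  }
}
tab <- do.call(rbind, rows)
trend <- concentration_trend(tab)
print(trend, digits = 4)
message(sprintf("Bare-DNA anchor (xi0) recovered at: %s nm",
                paste(round(trend$xi0, 1), collapse = ", ")))

write.csv(tab, "results/concentration_estimates.csv", row.names = FALSE)
write.csv(trend, "results/concentration_trend.csv", row.names = FALSE)
message("Wrote results/concentration_estimates.csv and results/concentration_trend.csv")
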