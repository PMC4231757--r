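# tpmkit

Single-molecule mechanics of DNA tethers: tethered particle motion (TPM)
and optical-tweezers force-extension analysis of protein-induced DNA
stiffening and force-triggered condensation.

## What it is for

Bacterial nucleoid-structuring proteins such as H-NS (with its cofactor
Hha) change the mechanical state of the DNA they coat: they can stiffen it
into filaments or bridge it into a condensed state, and the transition can
be triggered by mechanical tension. Two desk-scale observables report these
states:

* **TPM** — a micron bead tethered by a single DNA molecule explores a disc
  whose RMS radius encodes the DNA's stiffness. Under the Gaussian-chain
  approximation,

  $$R_{\mathrm{RMS}} = \sqrt{\tfrac{L_C\xi}{3}\Big(2 +
  \tfrac{4N_R}{\sqrt{\pi}\,\mathrm{erf}(N_R)}\Big)}, \qquad
  N_R = R\big/\sqrt{L_C\xi/3},$$

  which `tpmkit` inverts to estimate the persistence length $\xi$ from the
  measured excursion, accounting for the bead radius $R$.
* **Force-extension** — stretching the tether with optical tweezers and
  fitting the Marko–Siggia worm-like chain,

  $$f = \frac{k_BT}{\xi}\left(\frac{1}{4(1-z/L_C)^2} - \frac14 +
  \frac{z}{L_C}\right),$$

  with the contour length $L_C$ fixed (intact tether) or free (condensing
  tether), plus a nested-model F-test deciding which is warranted.
* **Collapse kinetics** — after a force trigger, the windowed RMS of a
  condensing tether relaxes as $R_\infty + (R_0-R_\infty)e^{-t/\tau}$;
  `tpmkit` smooths, ensemble-averages and fits release-aligned
  trajectories, classifies non-collapsing controls as such, and reports
  compaction ratios $R_\infty/R_0$ and late-time RMS histograms.

The package also contains the full supporting pipeline (trajectory IO,
drift filtering, 4 s windowed RMS, circularity screening for multiple
tethers, stuck-bead event masking), a synthetic-data generator
(Ornstein–Uhlenbeck tethered bead, noisy worm-like-chain sweeps, rendered
bead image stacks with centroid tracking) that emulates every input the
analysis consumes, and numbered analysis scripts under `analysis/` that
run the whole study on synthetic data.

## Worked example

A 5092 bp amplicon (0.34 nm/bp, so $L_C \approx 1.7\ \mu$m) on a 1 µm bead
showed an in-plane RMS excursion of 508 nm. What is its persistence length,
and does a simulated tether at the textbook stiffness reproduce it?

```r
library(tpmkit)

lc <- contour_length_from_bp(5092)        # 1731.28 nm
persistence_from_rms(508, lc, bead_radius = 500)
#> [1] 52.84806

# simulate 10 min of TPM at xi = 54 nm, then run the estimation pipeline
m <- tether_model(lc, 54, bead_radius = 500)
traj <- simulate_tpm(tpm_sim_config(model = m, duration = 600, seed = 7))
est <- persistence_from_trajectory(drift_filter(traj), lc, bead_radius = 500)
est
#> Persistence estimate 'sim': xi = 55.5 +/- 1.2 nm (R_RMS = 515.8 nm)
```

The inversion puts the measured tether at $\xi \approx 53$ nm (bare B-DNA),
and the closed-loop simulation recovers its input stiffness within the
stated error. Collapse kinetics work the same way end to end:

```r
series <- lapply(1:8, function(i) {
  cfg <- tpm_sim_config(model = m, rms0 = 500, duration = 1800,
                        collapse = list(tau_min = 7.5, plateau_fraction = 0.4),
                        seed = 100 + i)
  smooth_running_window(windowed_rms(simulate_tpm(cfg), 4), 60)
})
fit_exponential_decay(ensemble_average(aligned_ensemble(series, "100nM")))
#> Exponential collapse: tau = 7.63 +/- 0.19 min, R0 = 483 nm -> Rinf = 193 nm
```

The fitted time constant matches the simulated 7.5 min collapse and the
plateau sits at ~0.4 of the initial excursion — the moderate-compaction
regime, between one half and one third of the pre-stretch RMS.

## The analysis workflow

`analysis/01_simulate_experiments.R` … `06_concentration_trend.R` run the
study in order: generate the fixture suite (bulky trajectories under
`scratch/`, summaries under `results/`), screen all beads, calibrate the
bare-DNA persistence length by TPM and tweezers, fit the shrinking-contour
sweep sequence and its relative contour series, fit collapse kinetics and
histograms per condition, and fit persistence-vs-concentration trends.
Each script prints what it found and writes small CSV/JSON tables under
`results/`.

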