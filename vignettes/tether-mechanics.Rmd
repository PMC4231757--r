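---
title: "Tether mechanics: models, estimators and the synthetic experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tether mechanics: models, estimators and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmkit)
```

`tpmkit` analyses two complementary single-molecule readouts of DNA
mechanics — tethered particle motion (TPM) and optical-tweezers
force-extension sweeps — with the specific goal of quantifying
protein-induced changes of state: stiffening (a larger persistence length)
and force-triggered condensation (a shrinking excursion amplitude and
apparent contour length). This vignette explains the models the package
implements, the estimators built on them, the design choices that were
genuinely open, and what the bundled synthetic-data generator does and does
not emulate.

## The polymer model

A DNA tether of contour length $L_C$ and persistence length $\xi$ connects
a glass surface to a reporter microsphere of radius $R$. Two closed-form
results carry the whole analysis.

**Bead excursions at zero force.** Treating the unstressed DNA as a
Gaussian chain, the root-mean-square in-plane excursion of the bead centre
is

$$R_{\mathrm{RMS}} \;=\; \sqrt{\frac{L_C\,\xi}{3}\left(2 +
\frac{4N_R}{\sqrt{\pi}\,\operatorname{erf}(N_R)}\right)},
\qquad N_R = \frac{R}{\sqrt{L_C\,\xi/3}},$$

where the *excursion number* $N_R$ measures the bead radius against the
tether's fluctuation scale. For a point marker ($N_R \to 0$) the bracket
tends to 4 and the expression reduces to the free-chain in-plane value
$2\sqrt{L_C\xi/3}$; a large bead inflates the excursion because its centre
rides a hemisphere above the attachment point. The map $\xi \mapsto
R_{\mathrm{RMS}}$ is strictly increasing, so `persistence_from_rms()`
inverts it by bracketed root-finding on $\xi \in [0.1, 1000]$ nm (absolute
tolerance $10^{-4}$ nm); out-of-range targets produce an error stating the
attainable excursion range rather than a spurious root. The error function
is evaluated through `pnorm`, and the $N_R = 0$ limit is coded analytically
rather than as 0/0.

For the construct studied throughout — a 5092 bp amplicon at the canonical
B-DNA rise of 0.34 nm/bp ($L_C = 1731$ nm $\approx 1.7\ \mu$m) on a 1 µm
bead — inverting a measured excursion of 508 nm gives $\xi \approx 53$ nm,
squarely in the bare-DNA range:

```{r}
persistence_from_rms(508, contour_length_from_bp(5092), bead_radius = 500)
```

An independent check of the excursion formula ships with the test suite: a
freely-jointed chain of Kuhn length $2\xi$ with a bead on the upper
hemisphere, rejection-sampled against the surface, reproduces the closed
form within a few percent at $10^5$ accepted configurations.

**Force-extension.** Under tension the worm-like-chain interpolation

$$f(z) = \frac{k_BT}{\xi}\left(\frac{1}{4(1-z/L_C)^2} - \frac{1}{4} +
\frac{z}{L_C}\right), \qquad k_BT = 4.1\ \mathrm{pN\,nm},$$

is Hookean at small extension and diverges as $z \to L_C$. At fixed $L_C$
it is linear in $1/\xi$, so `fit_wlc_fixed_lc()` solves the least-squares
problem in closed form (a regression through the origin on $k_BT\,
g(z/L_C)$) with a delta-method standard error. The free-contour-length fit
is a bounded Levenberg–Marquardt optimisation, multi-started from
$\{1.05, 1.2, 1.5\} \times \max(z)$ because the likelihood has a local
minimum with $L_C$ pinned at its lower bound $\max(z)(1+10^{-3})$; a fit
that ends on the bound is flagged. Residuals are measured vertically (in
force): extension is set by the piezo stage while force is the noisy
readout. Point weights are uniform by default; the noise model is
homoscedastic and the sweeps analysed here stay below ~10 pN.

Whether a free contour length is *warranted* is decided by the nested-model
F-test in `compare_models()` (one extra parameter, $F_{1,n-2}$, default
$\alpha = 0.05$), with AIC reported alongside. On sweeps from an intact
tether the fixed model is preferred in ~95% of replicates; on sweeps whose
contour length has shrunk 30% the free model wins essentially always.

Units are nm, pN and seconds everywhere inside the package; minutes appear
only where collapse time constants are reported, because that is the
natural scale of the kinetics. $k_BT$ defaults to 4.1 pN nm and is an
explicit model field rather than a temperature parameterisation.

## The TPM pipeline

Raw trajectories (25 Hz bead centroids) pass through four stages:

1. **Drift filtering** (`drift_filter()`): subtraction of a centred moving
   average per axis. The window (default 20 s) must exceed the RMS window
   so genuine tether motion survives; on a pure OU signal the filter
   changes the windowed RMS by well under 3%. "High-pass filtering" is not
   defined more precisely by common TPM practice; moving-average
   subtraction was chosen for its flat passband and trivial impulse
   response, and the window is configurable.
2. **Windowed RMS** (`windowed_rms()`): dense (stride one frame) windows of
   4 s — 100 frames at 25 Hz — each centred on its own mean by default, so
   residual drift cannot inflate the excursion estimate. Global centring is
   available for drift-free records.
3. **Screening** (`circularity_screen()`, `detect_stuck_events()`).
   Circularity is defined as $\sqrt{\lambda_{\min}/\lambda_{\max}}$ of the
   position covariance — the ratio of RMS amplitudes along the principal
   axes — which is rotation invariant; a bead fails when the deviation from
   unity exceeds 10%. This covariance definition is one of several
   reasonable readings of "circularity"; it is stated prominently here
   because the screen's outcome depends on it. Stuck-bead events are
   step-like RMS drops exceeding 50% that persist for at least 10 s;
   because a genuine condensation collapse (time constant of minutes)
   changes the RMS only ~2% over that dwell, the detector cannot confuse
   the two. Flagged spans can be masked before fitting.
4. **Persistence estimation** (`persistence_from_trajectory()`): the mean
   windowed RMS is corrected for the finite-window centring bias (below),
   inverted through the excursion formula, and equipped with a standard
   error propagated from the sampling error of the mean RMS through the
   local derivative of the forward map. Stationarity is asserted by
   requiring first- and second-half mean RMS to agree within 10% — an
   estimate taken while a collapse is in progress is flagged and warned
   about, since a persistence length is only meaningful for a stationary
   tether.

**The finite-window correction.** Bead positions decorrelate over a
positional relaxation time $\tau_c \sim 0.1$ s, so the ~100 samples in a
4 s window are far from independent and the per-window mean soaks up a
predictable share of the true variance: for an AR(1) process with lag-one
autocorrelation $\rho$, $E[s^2_w] = \sigma^2(1 - S/n^2)$ with
$S = \sum_{i,j}\rho^{|i-j|}$, about a 5% variance deficit at
$\tau_c = 0.1$ s — which maps through the inversion to a 5–8% systematic
underestimate of $\xi$. The package estimates $\rho$ from the trajectory
itself and divides the deficit out (`bias_correction = TRUE`). No
additional factor is applied for the drift filter: it removes strictly
lower-frequency power whose in-window component the centring subtracts
anyway, and composing both corrections demonstrably overcorrects. With the
correction in place, full-pipeline recovery of simulated tethers is
unbiased to within sampling error across $\xi = 30$–200 nm. No camera-blur
(exposure-time) correction is applied, matching the acquisition being
emulated.

## Condensation kinetics

Collapse experiments give release-aligned windowed-RMS series ($t = 0$ at
trap release). The analysis mirrors how such data are presented: each
series is smoothed by a 60 s running window, the ensemble is averaged
pointwise (`ensemble_average()`, which tracks per-point counts), and the
average is fitted by

$$R(t) = R_\infty + (R_0 - R_\infty)\,e^{-t/\tau},$$

with $\tau$ reported in minutes. Fitting the smoothed ensemble average —
rather than averaging per-trajectory fits — is the package default because
the averaged curve is the object the exponential describes; per-trajectory
fitting remains available by passing individual series. The offset form is
an interpretation of "decaying exponential"; a zero-offset variant
(`zero_offset = TRUE`) is selectable. A 60 s window against a ~7.5 min
time constant biases the fitted $\tau$ by well under 2%.

**Identifiability.** A flat control series must not be awarded a time
constant. Three safeguards matter: (i) parameter standard errors are
inflated by the AR(1) effective-sample-size factor
$\sqrt{(1+\rho)/(1-\rho)}$ estimated from the residuals, because dense
smoothed RMS samples are massively autocorrelated and nominal errors
would be absurdly optimistic; (ii) a fit is flagged unidentifiable when
the relative error of $\tau$ exceeds 50%, when $\tau$ exceeds five times
the record, or when the amplitude is not resolved above twice its error;
(iii) the optimiser is kept away from the degenerate $\tau \to 0$ basin
(indistinguishable from a level shift) by a floor of 0.5% of the record
length. In a flagged fit the reported levels revert to model-free
head/tail means, since along the $\tau \to \infty$ ramp degeneracy the
exponential's own level parameters are arbitrary. On simulated flat
ensembles this classification is error-free over 50 seeds, while genuine
collapses are recovered within 10%.

Late-time state is summarised two ways: `histogram_gaussian_fit()` pools
all windowed-RMS samples beyond 15 min across an ensemble and fits a
Gaussian by maximum likelihood (pooling granularity is a choice; per-series
histograms would need far longer records), and `compaction_ratio()` reports
$R_\infty/R_0$ — between one half and one third for a moderate collapse,
deeper at higher protein concentration. `concentration_trend()` provides
the descriptive saturating-exponential interpolation
$\xi(c) = \xi_\infty - (\xi_\infty - \xi_0)e^{-c/c_0}$ across protein
concentrations; it is an interpolation, not a binding model.

## The synthetic experiment

`simulate_tpm()` generates each in-plane axis as a mean-reverting
(Ornstein–Uhlenbeck) Gaussian process with correlation time $\tau_c$
(default 0.1 s, typical for a micron bead on a ~1.7 µm tether; it sets the
effective sample size but not the stationary amplitude) and stationary
per-axis deviation $\sigma_{ax}(t) = R_{\mathrm{RMS}}(t)/\sqrt{2}$, so the
long-run in-plane RMS matches the excursion formula by construction — the
generator and the analysis share the Gaussian-chain assumption
deliberately, which is exactly what makes closed-loop recovery tests
meaningful. Collapse is modelled as an exponential relaxation of the
amplitude to a plateau fraction: the *observable* the kinetic analysis
fits, not a mechanistic bridging process. Drift (linear or random walk),
a discrete stuck-bead amplitude drop, and per-axis anisotropy (the
multiple-tether signature) can be superimposed; every record is
reproducible from its integer seed.

What the generator does **not** emulate — and what passing tests therefore
do not certify about laboratory data: the non-Gaussian statistics of real
excursions near the wall, camera exposure blur, localisation noise,
hydrodynamic coupling to the surface, and any mechanistic
nucleation/zipping kinetics of the protein filament. Conclusions about
estimator bias and classification error transfer to real data only to the
extent that these effects are small at the scales involved.

`simulate_fx()` evaluates the force law on a fractional-extension grid and
adds Gaussian force noise (default $\sigma = 0.2$ pN). The default grid
spans 0.10–0.95 of the contour length: near its top the restoring force at
$\xi \approx 53$ nm reaches ~8 pN, consistent with sweeps acquired up to
the ~10 pN range, and it is this high-force shoulder that pins the
persistence length to a few percent. Simulated forces are not truncated at
zero — a transducer near zero tension scatters on both sides of zero, and
truncation measurably biases the fitted noise scale. A shrink schedule
emits one curve per time point at its scheduled contour length (fractions
rescaled per curve by default; a fixed absolute grid is available and is
validated against the smallest scheduled contour length).
`make_fixture_suite()` writes the full canonical set — control, 100 nM-like
($\tau = 7.5$ min to a 0.4 plateau), 200 nM-like ($\tau = 7.3$ min to a
0.15 plateau, the order-of-magnitude compaction case), a non-condensing
mutant-cofactor ensemble, screening edge cases and the shrinking sweep
sequence — with a JSON manifest of ground truths.

`render_bead_frames()`/`track_centroid()` close the loop from images: a
2-D Gaussian spot (real bright-field bead images have ring structure, but
thresholded centroiding is insensitive to this at the tested SNRs) plus
pixel noise, tracked by intensity-weighted centroiding above 50% of the
background-subtracted peak, at a default 100 nm/px. The image path
reproduces position-level excursion statistics within a few percent at
SNR ≥ 10.

## Problem sizes and reproducibility

The shipped analysis scripts and the acceptance script use 30 min records
at 25 Hz (45 000 frames per trajectory), ensembles of 8 collapsing
trajectories, 50 seed replicates for kinetic recovery and 200 replicates
for force-extension recovery — sizes chosen to put the Monte-Carlo error of
every recovered quantity well inside the tolerance it is judged against.
All randomness flows from explicit integer seeds; identical configurations
and seeds reproduce byte-identical fixtures.

## Known limitations

* The excursion formula is a Gaussian-chain approximation: accurate for an
  unstressed ~5 kb tether, but increasingly crude for short tethers
  ($L_C \lesssim 10\,\xi$) or very large excursion numbers.
* The WLC interpolation deviates from the exact worm-like chain by up to a
  few percent at intermediate forces and ignores enthalpic stretching above
  ~10 pN; fits of sweeps reaching tens of pN would need an extensible
  model, which is out of scope.
* Collapse is summarised by a single exponential; multi-stage or stalled
  collapses will show up as lack of fit, not as extra parameters.
* The minimum detectable collapse amplitude is set by the identifiability
  safeguards: shallow (<10%) amplitude changes are typically flagged
  rather than quantified.
* Irreversibility of the collapsed state is recorded only as small
  refitted contour lengths; no hysteresis model is provided.
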