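Package: tpmkit
Title: Tethered Particle Motion and Force-Extension Analysis of DNA Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers the mechanical state of single DNA tethers from
    tethered particle motion (TPM) trajectories and optical-tweezers
    force-extension sweeps. Provides the Gaussian-chain inversion of
    in-plane bead excursions to persistence length (with the excursion-number
    bead correction), Marko-Siggia worm-like-chain fitting with fixed or
    free contour length plus nested-model comparison, trajectory screening
    (circularity, stuck-bead events) and drift correction, windowed-RMS
    condensation kinetics (running-window smoothing, ensemble averaging,
    exponential collapse fits, Gaussian excursion histograms, compaction
    ratios), and a matched synthetic-data generator (mean-reverting tethered
    bead process, noisy force-extension sweeps, rendered bead image stacks)
    so the entire pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
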