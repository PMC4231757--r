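#!/usr/bin/env Rscript
# Generate the synthetic single-molecule experiments everything downstream
# consumes: control and collapsing TPM ensembles (100 nM-like and 200 nM-like
# Hha/H-NS conditions plus a non-functional-mutant ensemble), screening
# edge cases (anisotropic, stuck bead), and a shrinking-contour
# force-extension sweep sequence. Trajectories are bulky, so they live under
# scratch/; a small summary goes to results/.

library(tpmkit)

fix_dir <- "scratch/fixtures"
dir.create("results", showWarnings = FALSE)

message("Writing fixture suite to ", fix_dir, " (seed 42, 30 min records)...")
man <- make_fixture_suite(fix_dir, seed = 42, duration = 1800)

n_files <- length(list.files(fix_dir, pattern = "\\.csv$"))
message(sprintf("  %d CSV files; ensembles: %s", n_files,
                paste(names(man$ensembles), collapse = ", ")))
message(sprintf("  collapse truths: tau = %.1f min (100 nM), %.1f min (200 nM); plateaus %.2f / %.2f",
                man$ensembles$hha_hns_100nM$tau_min,
                man$ensembles$hha_hns_200nM$tau_min,
                man$ensembles$hha_hns_100nM$plateau_fraction,
                man$ensembles$hha_hns_200nM$plateau_fraction))

summary <- list(
  fixture_dir = fix_dir,
  n_files = n_files,
  seed = man$seed,
  duration_s = man$duration_s,
  ensembles = lapply(man$ensembles, function(e)
    e[setdiff(names(e), "files")]),
  force_extension_relative_Lc = man$force_extension$relative_Lc)
jsonlite::write_json(summary, "results/fixture_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Wrote results/fixture_summary.json")
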