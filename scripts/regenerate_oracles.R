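#!/usr/bin/env Rscript
# Regenerates the exhaustive-oracle expected-output files for the curated
# fixtures under inst/extdata/oracles/.  Run from the repository root
# after any change to the fixtures; the files are never hand-edited.

suppressPackageStartupMessages(library(boolscape))

out_dir <- file.path("inst", "extdata", "oracles")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

fx <- curated_fixtures()

# tumorigenesis fixture: full exhaustive robustness trajectory
tj <- robustness_trajectory(fx$tumorigenesis$net, "disease",
                            fx$tumorigenesis$sequence,
                            fx$tumorigenesis$config, mode = "exhaustive")
jsonlite::write_json(
  list(step = tj$step, n_attractors = tj$n_attractors,
       top5_mean_basin = tj$top5_mean_basin, score = tj$score),
  file.path(out_dir, "tumorigenesis_trajectory.json"),
  digits = NA, pretty = TRUE)

# toggle fixture: exhaustive landscape summary
tog <- build_landscape(fx$toggle$net, "disease", mode = "exhaustive")
jsonlite::write_json(
  as.list(tidy(tog)[, c("id", "period", "basin_count")]),
  file.path(out_dir, "toggle_landscape.json"),
  digits = NA, pretty = TRUE)

# frozen fixture: activities before/after restoring the driver
st <- motif_stability(fx$frozen$net, "disease", fx$frozen$motif_nodes,
                      fx$frozen$perturbation, mode = "exhaustive")
jsonlite::write_json(
  as.list(st[, c("node", "activity_baseline", "activity_perturbed")]),
  file.path(out_dir, "frozen_activities.json"),
  digits = NA, pretty = TRUE)

cat("oracle files written to", out_dir, "\n")
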