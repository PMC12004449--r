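#!/usr/bin/env Rscript
# Generate the synthetic study systems: a 7-helix CG bundle in a 3:1
# POPE:POPG bilayer with the cardiolipin analog (CDL) at 0, 5 and 10 mol %.
# The 5% and 10% systems carry two planted binding sites with residence
# times of 1 and 2 us; ground truth is saved next to the trajectories.

suppressPackageStartupMessages(library(lipidsites))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed0 <- 20240901

sites <- list(planted_site(c(2, 3, 4, 5), k_on = 1e-4, k_off_true = 1e-3),
              planted_site(c(32, 33, 34, 35), k_on = 1e-4,
                           k_off_true = 5e-4))

for (frac in c(0, 0.05, 0.10)) {
  tag <- sprintf("cdl%02d", round(100 * frac))
  cfg <- synthetic_config(
    n_lipids_total = 128, mole_fraction_minority = frac,
    n_frames = 2000, frame_dt = 10, seed = seed0 + round(100 * frac),
    sites = if (frac > 0) sites else list())
  toy <- build_toy_system(cfg, prefix = file.path(out_dir, tag))
  truth <- list(
    mole_fraction = frac,
    n_lipids = as.list(cfg$n_lipids_by_species),
    site_residues = toy$truth$site_residues,
    tau_true_us = if (frac > 0) c(1, 2) else numeric(0))
  jsonlite::write_json(truth, file.path(out_dir, paste0(tag, "_truth.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cat(sprintf(
    "%s: %d frames x %d beads (%.0f us), %d CDL lipids, %d planted sites -> %s.{gro,dcd}\n",
    tag, cfg$n_frames, dim(toy$system$coords)[1],
    max(toy$system$times) / 1000, cfg$n_lipids_by_species[["CDL"]],
    length(cfg$sites), file.path(out_dir, tag)))
}
cat("done: trajectories are 20 us at a 10 ns stride; the first 2 us are\n")
cat("equilibration-like and are trimmed by the downstream scripts.\n")
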