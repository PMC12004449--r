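#!/usr/bin/env Rscript
# Dual-cutoff contact detection for the CDL-containing systems: trim the
# first 2 us, detect (lipid molecule, residue) contacts with the 5/7 A
# hysteresis, and write the event tables.

suppressPackageStartupMessages(library(lipidsites))

sim_dir <- "results/sim"
out_dir <- "results/contacts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (tag in c("cdl05", "cdl10")) {
  sys <- load_system(file.path(sim_dir, paste0(tag, ".gro")),
                     file.path(sim_dir, paste0(tag, ".dcd")),
                     frame_dt = 10)
  sys <- trim_trajectory(sys, 2000)
  series <- detect_contacts(sys, cg_selection(lipid_species = "CDL"),
                            cutoff_lower = 5, cutoff_upper = 7)
  ev <- events_from_series(series)
  write_events_csv(ev, series$frame_dt, file.path(out_dir,
                                                  paste0(tag, "_events.csv")))
  saveRDS(series, file.path(out_dir, paste0(tag, "_series.rds")))
  cat(sprintf(
    "%s: %d frames analyzed, %d contact events on %d residues (%d censored)\n",
    tag, dim(series$occupancy)[3], nrow(ev),
    length(unique(ev$residue)), sum(ev$censored)))
}
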