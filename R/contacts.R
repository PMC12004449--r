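#' Detect lipid-residue contacts with a dual-cutoff scheme
#'
#' For every (lipid molecule, protein residue) pair and frame, the minimum
#' bead-bead minimum-image distance is compared against two cutoffs: a
#' contact STARTS at the first frame where the distance drops below
#' `cutoff_lower` and PERSISTS through every subsequent frame where it
#' stays below `cutoff_upper`, ending at the first frame at or above
#' `cutoff_upper`. The hysteresis suppresses boundary rattling: brief
#' excursions into the 5-7 Angstrom shell do not break a contact, and
#' grazing approaches that never come below the lower cutoff never start
#' one. Contact is molecule-level for the lipid (any of its beads) and
#' residue-level for the protein (any bead of the residue).
#'
#' @param system a `cg_system` (trim the equilibration segment first).
#' @param selection a [cg_selection()] naming the lipid species of
#'   interest.
#' @param cutoff_lower,cutoff_upper the dual cutoffs (Angstrom), lower <=
#'   upper; defaults 5 and 7. Setting them equal reduces the scheme to a
#'   single cutoff.
#' @return A `contact_series` whose rows are the molecules of the selected
#'   lipid species (molecule ids in `lipid_ids`) and whose columns are the
#'   protein residues (0-based ids in `residue_ids`).
#' @export
detect_contacts <- function(system, selection, cutoff_lower = 5,
                            cutoff_upper = 7) {
  stopifnot(inherits(system, "cg_system"),
            inherits(selection, "cg_selection"))
  if (cutoff_lower <= 0 || cutoff_lower > cutoff_upper)
    stop("cutoffs must be positive with lower <= upper", call. = FALSE)
  dmin <- min_residue_distances(system, selection)
  occ <- apply_dual_cutoff(dmin$dist, cutoff_lower, cutoff_upper)
  contact_series(occ, frame_dt = frame_dt_of(system),
                 lipid_ids = dmin$lipid_ids, residue_ids = dmin$residue_ids,
                 cutoff_lower = cutoff_lower, cutoff_upper = cutoff_upper)
}

frame_dt_of <- function(system) {
  if (n_frames(system) < 2) return(1)
  diff(system$times[1:2])
}

# Per-frame minimum bead-bead distance for every (lipid molecule, protein
# residue) pair. Returns dist: array n_lipid x n_residue x n_frames.
min_residue_distances <- function(system, selection) {
  prot_beads <- beads_of_species(system, selection$protein_species)
  lip_beads <- beads_of_species(system, selection$lipid_species)
  if (length(prot_beads) == 0 || length(lip_beads) == 0)
    stop("invalid selection: empty protein or lipid bead set", call. = FALSE)
  res_ids <- system$bead_residue[prot_beads]
  if (!is.null(selection$protein_residues)) {
    keep <- res_ids %in% selection$protein_residues
    prot_beads <- prot_beads[keep]
    res_ids <- res_ids[keep]
    if (length(prot_beads) == 0)
      stop("invalid selection: no protein beads in residue subset",
           call. = FALSE)
  }
  mol_ids <- system$bead_molecule[lip_beads]
  res_levels <- sort(unique(res_ids))
  mol_levels <- sort(unique(mol_ids))
  res_grp <- match(res_ids, res_levels)
  mol_grp <- match(mol_ids, mol_levels)
  nf <- n_frames(system)
  dist <- array(NA_real_, c(length(mol_levels), length(res_levels), nf))
  for (f in seq_len(nf)) {
    d2 <- min_image_dist2_matrix(
      system$coords[lip_beads, , f, drop = FALSE][, , 1, drop = TRUE],
      system$coords[prot_beads, , f, drop = FALSE][, , 1, drop = TRUE],
      system$box[f, ])
    if (is.null(dim(d2))) d2 <- matrix(d2, length(lip_beads))
    d2 <- group_min_rows(d2, mol_grp)
    d2 <- t(group_min_rows(t(d2), res_grp))
    dist[, , f] <- sqrt(d2)
  }
  list(dist = dist, lipid_ids = mol_levels, residue_ids = res_levels)
}

# Hysteresis state machine, vectorized over channels.
apply_dual_cutoff <- function(dist, lower, upper) {
  d <- dim(dist)
  occ <- array(FALSE, d)
  prev <- matrix(FALSE, d[1], d[2])
  for (f in seq_len(d[3])) {
    df <- dist[, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(df) <- d[1:2]
    prev <- (df < lower) | (prev & (df < upper))
    occ[, , f] <- prev
  }
  occ
}

#' Apply the dual-cutoff rule to a per-frame distance trace
#'
#' Convenience wrapper used for forced examples and single-channel checks:
#' takes one vector of per-frame minimum distances and returns the event
#' table implied by the hysteresis rule.
#'
#' @param distances numeric vector of per-frame minimum distances
#'   (Angstrom).
#' @param cutoff_lower,cutoff_upper the dual cutoffs.
#' @param frame_dt time per frame (ns).
#' @return data.frame of events as in [events_from_series()].
#' @export
contacts_from_distances <- function(distances, cutoff_lower = 5,
                                    cutoff_upper = 7, frame_dt = 1) {
  dist <- array(distances, c(1, 1, length(distances)))
  occ <- apply_dual_cutoff(dist, cutoff_lower, cutoff_upper)
  events_from_series(contact_series(occ, frame_dt = frame_dt))
}

#' Write contact events to CSV
#'
#' Tabular event list with times in ns: one row per contact event
#' (`lipid_id`, `residue` 1-based, `start_ns`, `end_ns`, `censored`).
#'
#' @param events event table from [events_from_series()].
#' @param frame_dt time per frame (ns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, frame_dt, path) {
  out <- data.frame(lipid_id = events$lipid_id,
                    residue = events$residue + 1L,
                    start_ns = events$start_frame * frame_dt,
                    end_ns = events$end_frame * frame_dt,
                    censored = events$censored)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
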