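#' Load a topology + trajectory into a cg_system
#'
#' Reads a GRO topology (bead names, residue ids, species labels from
#' residue names) and a DCD trajectory (coordinates and per-frame box),
#' converts everything to internal units (Angstrom, ns), and builds the
#' residue/molecule maps. Molecules are contiguous runs of the same residue
#' id, except that all beads of species in `protein_species` are collapsed
#' into a single protein molecule whose residues keep their own ids.
#'
#' @param topology_path GRO file path.
#' @param trajectory_path DCD file path.
#' @param frame_dt time between saved frames (ns); DCD files do not carry
#'   time in physical units, so the stride must be supplied.
#' @param protein_species residue names treated as the protein (all mapped
#'   to molecule species `"protein"`).
#' @return A `cg_system`.
#' @export
load_system <- function(topology_path, trajectory_path, frame_dt = 1,
                        protein_species = c("PRO", "PROT")) {
  if (!file.exists(topology_path))
    stop("topology file not found: ", topology_path, call. = FALSE)
  if (!file.exists(trajectory_path))
    stop("trajectory file not found: ", trajectory_path, call. = FALSE)
  top <- read_gro(topology_path)
  trj <- read_dcd(trajectory_path)
  nb <- nrow(top$coords)
  if (dim(trj$coords)[1] != nb)
    stop(sprintf(
      "bead count mismatch: topology has %d beads, trajectory has %d",
      nb, dim(trj$coords)[1]), call. = FALSE)
  is_prot <- top$resname %in% protein_species
  # residue index: new residue whenever the (resid, resname) pair changes
  key <- paste(top$resid, top$resname)
  new_res <- c(TRUE, key[-1] != key[-nb])
  bead_residue <- cumsum(new_res) - 1L
  # molecules: protein beads are one molecule; each lipid residue is one
  bead_molecule <- integer(nb)
  if (any(is_prot)) {
    bead_molecule[is_prot] <- 0L
    lip_res <- bead_residue[!is_prot]
    bead_molecule[!is_prot] <- as.integer(factor(lip_res,
                                                 levels = unique(lip_res)))
  } else {
    bead_molecule <- as.integer(factor(bead_residue,
                                       levels = unique(bead_residue))) - 1L
  }
  mol_first <- !duplicated(bead_molecule)
  molecule_species <- ifelse(is_prot[mol_first], "protein",
                             top$resname[mol_first])
  nfr <- dim(trj$coords)[3]
  cg_system(
    coords = trj$coords,
    box = trj$box,
    times = (seq_len(nfr) - 1) * frame_dt,
    bead_residue = bead_residue,
    bead_molecule = bead_molecule,
    bead_name = top$atom_name,
    molecule_species = molecule_species
  )
}

#' Discard an initial equilibration segment
#'
#' Removes all frames earlier than `t_discard` (ns) and re-origins the
#' remaining frame times to start at 0. Analyses conventionally drop the
#' first stretch of a production run to let the system decorrelate from its
#' starting configuration (2 us is a typical choice for coarse-grained
#' membrane systems).
#'
#' @param system a `cg_system`.
#' @param t_discard time to discard from the start (ns), `>= 0`.
#' @return A trimmed `cg_system`.
#' @export
trim_trajectory <- function(system, t_discard) {
  if (t_discard < 0) stop("t_discard must be >= 0", call. = FALSE)
  keep <- which(system$times >= t_discard)
  if (length(keep) == 0)
    stop("trimming removed every frame (t_discard exceeds trajectory length)",
         call. = FALSE)
  if (length(keep) == n_frames(system) && t_discard == 0) return(system)
  cg_system(
    coords = system$coords[, , keep, drop = FALSE],
    box = system$box[keep, , drop = FALSE],
    times = system$times[keep] - system$times[keep[1]],
    bead_residue = system$bead_residue,
    bead_molecule = system$bead_molecule,
    bead_name = system$bead_name,
    molecule_species = system$molecule_species
  )
}
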