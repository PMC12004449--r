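#' Coarse-grained system container
#'
#' A `cg_system` holds everything the analysis layer reads: bead coordinates
#' per frame, the residue/molecule/species maps from the topology, the
#' orthorhombic box per frame, and the frame times. Coordinates and box
#' lengths are stored in Angstrom, times in nanoseconds; unit conversion
#' happens only at the I/O boundary (GRO files are in nm).
#'
#' @param coords numeric array `n_beads x 3 x n_frames` (Angstrom).
#' @param box numeric matrix `n_frames x 3` of orthorhombic box lengths
#'   (Angstrom), or a length-3 vector recycled to all frames.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param bead_residue integer vector, 0-based residue index per bead.
#' @param bead_molecule integer vector, 0-based molecule index per bead.
#' @param bead_name character vector of bead (atom) names per bead.
#' @param molecule_species character vector, species label per molecule
#'   (e.g. `"protein"`, `"POPE"`, `"CDL"`).
#'
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(coords, box, times, bead_residue, bead_molecule,
                      bead_name, molecule_species) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_beads x 3 x n_frames array", call. = FALSE)
  n_beads <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L)
    stop("box must be n_frames x 3", call. = FALSE)
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  if (length(times) != n_frames)
    stop("times must have one entry per frame", call. = FALSE)
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  for (v in list(bead_residue, bead_molecule, bead_name)) {
    if (length(v) != n_beads)
      stop("per-bead vectors must have length n_beads", call. = FALSE)
  }
  n_mol <- max(bead_molecule) + 1L
  if (length(molecule_species) != n_mol)
    stop("molecule_species must have one label per molecule", call. = FALSE)
  structure(list(
    coords = coords,
    box = box,
    times = as.numeric(times),
    bead_residue = as.integer(bead_residue),
    bead_molecule = as.integer(bead_molecule),
    bead_name = as.character(bead_name),
    molecule_species = as.character(molecule_species)
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(
    "cg_system: %d beads, %d residues, %d molecules, %d frames (%.1f-%.1f ns)\n",
    dim(x$coords)[1], length(unique(x$bead_residue)),
    length(x$molecule_species), dim(x$coords)[3],
    x$times[1], x$times[length(x$times)]))
  tab <- table(x$molecule_species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(system) dim(system$coords)[3]
n_beads <- function(system) dim(system$coords)[1]

#' Analysis selection
#'
#' Names the protein residues and the lipid species the contact analysis
#' should look at. Protein residues are 0-based internally (reports are
#' 1-based, matching conventional residue numbering).
#'
#' @param protein_species species label(s) treated as protein.
#' @param lipid_species species label of the lipid of interest (e.g. the
#'   cardiolipin analog).
#' @param background_species other lipid species labels (used by membrane
#'   descriptors; ignored by contact detection).
#' @param protein_residues optional integer vector restricting the analysis
#'   to a subset of 0-based protein residue indices; `NULL` means all.
#' @return An object of class `cg_selection`.
#' @export
cg_selection <- function(protein_species = "protein", lipid_species,
                         background_species = character(),
                         protein_residues = NULL) {
  if (missing(lipid_species) || length(lipid_species) != 1L)
    stop("lipid_species must be a single species label", call. = FALSE)
  if (lipid_species %in% protein_species)
    stop("protein and lipid selections must be disjoint", call. = FALSE)
  structure(list(
    protein_species = protein_species,
    lipid_species = lipid_species,
    background_species = background_species,
    protein_residues = if (is.null(protein_residues)) NULL else
      as.integer(protein_residues)
  ), class = "cg_selection")
}

# Beads belonging to molecules of the given species labels.
beads_of_species <- function(system, species) {
  which(system$molecule_species[system$bead_molecule + 1L] %in% species)
}

# Restore the caller's RNG state after running `expr` under `seed`.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
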