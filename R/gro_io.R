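#' Write a GRO topology/coordinate file
#'
#' Writes one frame of a `cg_system` in GROMACS GRO fixed-width format.
#' GRO files are in nanometers; internal coordinates (Angstrom) are divided
#' by 10 on the way out. Residue names are the molecule species labels
#' (truncated to 5 characters), so a round trip preserves the
#' residue/molecule/species maps.
#'
#' @param system a `cg_system`.
#' @param path output file path.
#' @param frame 1-based frame index to write (default first).
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, path, frame = 1L) {
  xyz <- system$coords[, , frame, drop = FALSE][, , 1] / 10  # A -> nm
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  nb <- nrow(xyz)
  resid <- system$bead_residue + 1L                    # 1-based in file
  sp <- system$molecule_species[system$bead_molecule + 1L]
  resname <- substr(ifelse(sp == "protein", "PRO", sp), 1, 5)
  lines <- c(
    sprintf("cg_system frame %d, t= %.4f", frame, system$times[frame]),
    sprintf("%5d", nb),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid %% 100000L, resname, substr(system$bead_name, 1, 5),
            seq_len(nb) %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", system$box[frame, 1] / 10,
            system$box[frame, 2] / 10, system$box[frame, 3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file
#'
#' Parses the fixed-width GRO dialect (single frame). Returns coordinates in
#' Angstrom plus the per-bead residue id, residue name and atom name columns
#' needed to reconstruct molecule and species maps.
#'
#' @param path file path.
#' @return list with `coords` (n x 3, Angstrom), `box` (length 3, Angstrom),
#'   `resid` (integer), `resname`, `atom_name`, `title`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("not a GRO file: fewer than 3 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3)
    stop("malformed GRO file: bad atom count", call. = FALSE)
  at <- lines[3:(n + 2)]
  fw <- function(s, a, b) substr(s, a, b)
  coords <- cbind(as.numeric(fw(at, 21, 28)),
                  as.numeric(fw(at, 29, 36)),
                  as.numeric(fw(at, 37, 44))) * 10  # nm -> A
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3] * 10
  list(coords = coords, box = box,
       resid = as.integer(fw(at, 1, 5)),
       resname = trimws(fw(at, 6, 10)),
       atom_name = trimws(fw(at, 11, 15)),
       title = lines[1])
}
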