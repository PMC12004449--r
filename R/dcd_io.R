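#' Write a CHARMM-style DCD trajectory
#'
#' Writes coordinates (Angstrom, single precision) with a unit-cell block
#' per frame (orthorhombic: lengths A, B, C with 90 degree angles). The
#' layout follows the CHARMM/NAMD binary DCD convention (Fortran
#' record-length markers, 'CORD' header, X/Y/Z blocks per frame) and is
#' readable by standard trajectory tools.
#'
#' @param coords array `n_beads x 3 x n_frames` (Angstrom).
#' @param box matrix `n_frames x 3` of box lengths (Angstrom).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, box, path) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nfr <- dim(coords)[3]
  nat <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nfr, 3, byrow = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4)
  # header record: 'CORD' + 20 control ints (nframes, istart, nsavc, nsteps,
  # ..., cryst flag at 11, CHARMM version at 20)
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[11] <- 1L   # unit cell present
  icntrl[20] <- 24L  # CHARMM format version
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(icntrl)
  wint(84)
  title <- formatC("Created by lipidsites", width = -80)
  wint(4 + 80)
  wint(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4 + 80)
  wint(4); wint(nat); wint(4)
  for (f in seq_len(nfr)) {
    # unit cell: A, cos(gamma), B, cos(beta), cos(alpha), C
    u <- c(box[f, 1], 0, box[f, 2], 0, 0, box[f, 3])
    wint(48)
    writeBin(as.numeric(u), con, size = 8)
    wint(48)
    for (k in 1:3) {
      wint(4 * nat)
      writeBin(as.numeric(coords[, k, f]), con, size = 4)
      wint(4 * nat)
    }
  }
  invisible(path)
}

#' Read a CHARMM-style DCD trajectory
#'
#' Minimal reader for the DCD files this package writes (CHARMM convention,
#' no fixed atoms, optional unit-cell block). Coordinates come back in
#' Angstrom.
#'
#' @param path file path.
#' @return list with `coords` (`n_beads x 3 x n_frames`) and `box`
#'   (`n_frames x 3` box lengths).
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n, size = 4)
  rec <- rint()
  if (rec != 84) stop("not a DCD file (bad header record)", call. = FALSE)
  tag <- readChar(con, 4)
  if (tag != "CORD") stop("not a coordinate DCD file", call. = FALSE)
  icntrl <- rint(20)
  rint()
  nfr <- icntrl[1]
  has_cell <- icntrl[20] != 0 && icntrl[11] == 1
  tlen <- rint()
  ntitle <- rint()
  if (ntitle > 0) readChar(con, 80 * ntitle)
  rint()
  rint(); nat <- rint(); rint()
  coords <- array(NA_real_, c(nat, 3, nfr))
  box <- matrix(NA_real_, nfr, 3)
  for (f in seq_len(nfr)) {
    if (has_cell) {
      rint()
      u <- readBin(con, "numeric", 6, size = 8)
      box[f, ] <- u[c(1, 3, 6)]
      rint()
    }
    for (k in 1:3) {
      rint()
      coords[, k, f] <- readBin(con, "numeric", nat, size = 4)
      rint()
    }
  }
  list(coords = coords, box = box)
}
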