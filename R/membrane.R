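#' Assign lipids to leaflets
#'
#' Per frame, each lipid is assigned to the upper or lower leaflet by the
#' z of its head bead relative to the instantaneous midplane (the mean z
#' over all lipid beads that frame). A head exactly at the midplane is
#' assigned by its tail direction (head above its own tail beads means
#' upper).
#'
#' @param system a `cg_system`.
#' @param head_bead bead name of the lipid head bead.
#' @param lipid_species species to assign; default all non-protein.
#' @return list: `leaflet` character matrix (`n_lipid x n_frames`,
#'   "upper"/"lower"), `lipids` (molecule ids), `midplane` (per-frame z).
#' @export
assign_leaflets <- function(system, head_bead = "HD", lipid_species = NULL) {
  if (is.null(lipid_species))
    lipid_species <- setdiff(unique(system$molecule_species), "protein")
  lip_beads <- beads_of_species(system, lipid_species)
  if (length(lip_beads) == 0) stop("no lipid beads found", call. = FALSE)
  heads <- lip_beads[system$bead_name[lip_beads] == head_bead]
  if (length(heads) == 0)
    stop("no head beads named '", head_bead, "'", call. = FALSE)
  lipids <- system$bead_molecule[heads]
  nfr <- n_frames(system)
  leaflet <- matrix(NA_character_, length(lipids), nfr)
  midplane <- numeric(nfr)
  for (f in seq_len(nfr)) {
    zs <- system$coords[lip_beads, 3, f]
    mid <- mean(zs)
    midplane[f] <- mid
    hz <- system$coords[heads, 3, f]
    up <- hz > mid
    tie <- hz == mid
    if (any(tie)) {
      for (i in which(tie)) {
        mol_beads <- lip_beads[system$bead_molecule[lip_beads] == lipids[i]]
        tail_z <- mean(system$coords[setdiff(mol_beads, heads[i]), 3, f])
        up[i] <- hz[i] > tail_z
      }
    }
    leaflet[, f] <- ifelse(up, "upper", "lower")
  }
  list(leaflet = leaflet, lipids = lipids, midplane = midplane)
}

#' Membrane thickness time series
#'
#' Per frame: the absolute difference between the mean z of upper-leaflet
#' head beads and the mean z of lower-leaflet head beads (phosphate-plane
#' separation — the simplest thickness definition consistent with CG head
#' beads).
#'
#' @param system a `cg_system`.
#' @param leaflets result of [assign_leaflets()]; computed if `NULL`.
#' @param head_bead head bead name.
#' @return numeric vector, thickness (Angstrom) per frame.
#' @export
membrane_thickness <- function(system, leaflets = NULL, head_bead = "HD") {
  if (is.null(leaflets)) leaflets <- assign_leaflets(system, head_bead)
  lip_beads <- beads_of_species(
    system, setdiff(unique(system$molecule_species), "protein"))
  heads <- lip_beads[system$bead_name[lip_beads] == head_bead]
  nfr <- n_frames(system)
  vapply(seq_len(nfr), function(f) {
    up <- leaflets$leaflet[, f] == "upper"
    if (!any(up) || all(up))
      stop("one leaflet is empty at frame ", f, call. = FALSE)
    abs(mean(system$coords[heads[up], 3, f]) -
          mean(system$coords[heads[!up], 3, f]))
  }, numeric(1))
}

# --- exact periodic 2D Voronoi by half-plane clipping ---------------------

# Clip convex polygon (matrix of vertices) by half-plane (x - m) . n <= 0.
clip_halfplane <- function(poly, m, n) {
  d <- (poly[, 1] - m[1]) * n[1] + (poly[, 2] - m[2]) * n[2]
  tol <- 1e-12 * max(abs(d), 1)
  inside <- d <= tol
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  nv <- nrow(poly)
  out <- matrix(NA_real_, nv + 4, 2)
  k <- 0L
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    if (inside[i]) { k <- k + 1L; out[k, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

shoelace_area <- function(poly) {
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Periodic 2D Voronoi cell areas
#'
#' Exact cell areas of the Voronoi tessellation of points in a periodic
#' rectangle. Each seed's cell starts from the half-box rectangle centered
#' on the seed (its cell with respect to its own periodic images) and is
#' clipped by the perpendicular-bisector half-plane against every periodic
#' image of every other seed (and the diagonal images of itself), nearest
#' first, stopping once no remaining image can cut the polygon. Areas sum
#' to the box area by construction, up to floating-point round-off.
#'
#' @param xy n x 2 matrix of seed positions.
#' @param box2 length-2 box (Lx, Ly).
#' @return numeric vector of cell areas.
#' @export
periodic_voronoi_areas <- function(xy, box2) {
  n <- nrow(xy)
  if (n < 1) stop("need at least one seed", call. = FALSE)
  shifts <- as.matrix(expand.grid(sx = c(-1, 0, 1) * box2[1],
                                  sy = c(-1, 0, 1) * box2[2]))
  areas <- numeric(n)
  # all images of all seeds
  imgs <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    cbind(xy[, 1] + shifts[s, 1], xy[, 2] + shifts[s, 2], seq_len(n),
          shifts[s, 1] == 0 && shifts[s, 2] == 0)))
  for (i in seq_len(n)) {
    p <- xy[i, ]
    hw <- box2 / 2
    poly <- cbind(p[1] + c(-hw[1], hw[1], hw[1], -hw[1]),
                  p[2] + c(-hw[2], -hw[2], hw[2], hw[2]))
    others <- imgs[!(imgs[, 3] == i & imgs[, 4] == 1), , drop = FALSE]
    d2 <- (others[, 1] - p[1])^2 + (others[, 2] - p[2])^2
    ord <- order(d2)
    for (o in ord) {
      q <- others[o, 1:2]
      # farthest polygon vertex from the seed bounds which images matter
      rmax2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if (d2[o] > 4 * rmax2) break
      m <- (p + q) / 2
      poly <- clip_halfplane(poly, m, q - p)
      if (nrow(poly) < 3) break
    }
    areas[i] <- shoelace_area(poly)
  }
  areas
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Per leaflet and frame: the head-bead xy positions of the leaflet's
#' lipids are tessellated (periodic in xy); transmembrane protein beads
#' near the leaflet's head plane are included as extra Voronoi seeds and
#' their cells excluded from the lipid mean, so the protein's in-plane
#' footprint does not inflate the APL.
#'
#' @param system a `cg_system`.
#' @param leaflets result of [assign_leaflets()]; computed if `NULL`.
#' @param head_bead head bead name.
#' @param frames frame indices to analyze (default all).
#' @param protein_z_window protein beads within this z distance (Angstrom)
#'   of the leaflet head plane become seeds.
#' @return data.frame with columns `frame`, `leaflet`, `apl` (Angstrom^2),
#'   `n_lipids`, `n_protein_seeds`, `area_check` (sum of all cell areas
#'   minus box area, should be ~0).
#' @export
area_per_lipid <- function(system, leaflets = NULL, head_bead = "HD",
                           frames = NULL, protein_z_window = 5) {
  if (is.null(leaflets)) leaflets <- assign_leaflets(system, head_bead)
  if (is.null(frames)) frames <- seq_len(n_frames(system))
  lip_beads <- beads_of_species(
    system, setdiff(unique(system$molecule_species), "protein"))
  heads <- lip_beads[system$bead_name[lip_beads] == head_bead]
  prot_beads <- beads_of_species(system, "protein")
  out <- list()
  for (f in frames) {
    box2 <- system$box[f, 1:2]
    for (side in c("upper", "lower")) {
      sel <- leaflets$leaflet[, f] == side
      if (sum(sel) < 3)
        stop("fewer than 3 lipids in ", side, " leaflet at frame ", f,
             call. = FALSE)
      hxy <- system$coords[heads[sel], 1:2, f, drop = FALSE][, , 1]
      if (is.null(dim(hxy))) hxy <- matrix(hxy, ncol = 2)
      hz <- mean(system$coords[heads[sel], 3, f])
      pseeds <- matrix(numeric(0), 0, 2)
      if (length(prot_beads)) {
        pz <- system$coords[prot_beads, 3, f]
        near <- abs(pz - hz) < protein_z_window
        if (any(near)) {
          pxy <- system$coords[prot_beads[near], 1:2, f, drop = FALSE][, , 1]
          if (is.null(dim(pxy))) pxy <- matrix(pxy, ncol = 2)
          pseeds <- pxy[!duplicated(round(pxy, 6)), , drop = FALSE]
        }
      }
      seeds <- rbind(hxy, pseeds)
      seeds[, 1] <- seeds[, 1] %% box2[1]
      seeds[, 2] <- seeds[, 2] %% box2[2]
      areas <- periodic_voronoi_areas(seeds, box2)
      n_lip <- nrow(hxy)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, leaflet = side, apl = mean(areas[seq_len(n_lip)]),
        n_lipids = n_lip, n_protein_seeds = nrow(pseeds),
        area_check = sum(areas) - prod(box2))
    }
  }
  do.call(rbind, out)
}

#' P2 order parameter of a set of bond vectors
#'
#' \eqn{P_2 = (3 \langle \cos^2\theta \rangle - 1) / 2} with theta the
#' angle between each vector and the z axis (the bilayer normal). 1 means
#' parallel to the normal, -0.5 in-plane, 0 isotropic.
#'
#' @param vectors n x 3 matrix of bond vectors.
#' @return P2 value.
#' @export
p2_of_vectors <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 3)
  len2 <- rowSums(vectors^2)
  cos2 <- vectors[, 3]^2 / len2
  (3 * mean(cos2) - 1) / 2
}

#' CG bond order parameters of a lipid species
#'
#' For each consecutive bead-bead bond of the species (bond i connects
#' bead i and i+1 in topology order), computes the P2 order parameter
#' against the z axis, averaged over all molecules of the species and over
#' frames. Bond vectors are minimum-image corrected.
#'
#' @param system a `cg_system`.
#' @param species lipid species label.
#' @param frames frame indices (default all).
#' @return data.frame with columns `bond` (1-based index), `p2`.
#' @export
order_parameters <- function(system, species, frames = NULL) {
  beads <- beads_of_species(system, species)
  if (length(beads) == 0) stop("species not found", call. = FALSE)
  mols <- split(beads, system$bead_molecule[beads])
  nb <- lengths(mols)
  if (any(nb < 2)) stop("species needs at least 2 beads per molecule",
                        call. = FALSE)
  if (length(unique(nb)) != 1)
    stop("molecules of one species must have equal bead counts",
         call. = FALSE)
  nbond <- nb[[1]] - 1L
  if (is.null(frames)) frames <- seq_len(n_frames(system))
  first <- vapply(mols, `[`, integer(1), 1)    # beads contiguous per mol
  p2 <- numeric(nbond)
  for (b in seq_len(nbond)) {
    vecs <- do.call(rbind, lapply(frames, function(f) {
      v <- system$coords[first + b, , f, drop = FALSE][, , 1] -
        system$coords[first + b - 1L, , f, drop = FALSE][, , 1]
      if (is.null(dim(v))) v <- matrix(v, ncol = 3)
      L <- system$box[f, ]
      for (k in 1:3) v[, k] <- v[, k] - L[k] * round(v[, k] / L[k])
      v
    }))
    p2[b] <- p2_of_vectors(vecs)
  }
  data.frame(bond = seq_len(nbond), p2 = p2)
}

#' Block-averaged standard deviation
#'
#' Standard deviation of block means of a (possibly autocorrelated) frame
#' series; with `block_size = 1` this is the plain frame-to-frame SD.
#'
#' @param x numeric series.
#' @param block_size frames per block.
#' @return SD of block means.
#' @export
block_sd <- function(x, block_size = 1) {
  if (block_size <= 1) return(stats::sd(x))
  nb <- floor(length(x) / block_size)
  if (nb < 2) return(NA_real_)
  means <- vapply(seq_len(nb), function(i)
    mean(x[((i - 1) * block_size + 1):(i * block_size)]), numeric(1))
  stats::sd(means)
}
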