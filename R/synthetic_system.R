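#' Define a planted lipid binding site
#'
#' Ground truth for parameter-recovery tests: a set of protein residues
#' that binds the minority lipid with first-order kinetics. `k_on` is the
#' association rate per free lipid, so the total binding flux scales with
#' the number of unbound minority lipids; `k_off_true` is the dissociation
#' rate whose inverse is the planted residence time.
#'
#' @param residue_ids 0-based protein residue indices (non-empty).
#' @param k_on association rate per free lipid (1/ns).
#' @param k_off_true dissociation rate (1/ns), `> 0`.
#' @param capture_radius how close (Angstrom) the bound lipid is held to
#'   the site beads.
#' @return An object of class `planted_site`.
#' @export
planted_site <- function(residue_ids, k_on, k_off_true, capture_radius = 5) {
  if (length(residue_ids) == 0) stop("residue_ids must be non-empty",
                                     call. = FALSE)
  if (k_off_true <= 0 || k_on <= 0) stop("rates must be positive",
                                         call. = FALSE)
  structure(list(residue_ids = as.integer(residue_ids), k_on = k_on,
                 k_off_true = k_off_true, capture_radius = capture_radius),
            class = "planted_site")
}

#' Configuration for the synthetic coarse-grained system
#'
#' Describes a toy transmembrane 7-helix bead bundle in a two-species
#' bilayer (3:1 POPE:POPG) plus a minority lipid species (the cardiolipin
#' analog, `"CDL"`) at a chosen mole fraction, with optional planted
#' binding sites. Defaults emulate a small patch of the study membrane:
#' minority fractions of 0, 5 or 10 mol %, a 7-column protein of 70
#' residues, and frames saved every 10 ns.
#'
#' @param n_lipids_total total lipid count (split over two leaflets).
#' @param mole_fraction_minority minority-lipid mole fraction (0, 0.05,
#'   0.10 are the study conditions; any value in `[0, 0.5)` is accepted).
#' @param box length-3 box (Angstrom).
#' @param n_frames number of saved frames, `>= 2`.
#' @param frame_dt time between frames (ns).
#' @param diffusion_coeff lateral lipid diffusion coefficient
#'   (Angstrom^2/ns).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param sites list of [planted_site()] objects with pairwise disjoint
#'   residue sets.
#' @param n_protein_residues protein residue count (one backbone bead per
#'   residue, split over 7 columns).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lipids_total = 128,
                             mole_fraction_minority = 0.10,
                             box = c(80, 80, 100),
                             n_frames = 2000, frame_dt = 10,
                             diffusion_coeff = 10, seed = 1,
                             sites = list(), n_protein_residues = 70) {
  if (mole_fraction_minority < 0 || mole_fraction_minority >= 0.5)
    stop("mole_fraction_minority must be in [0, 0.5)", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be positive", call. = FALSE)
  n_min <- round(n_lipids_total * mole_fraction_minority)
  n_bg <- n_lipids_total - n_min
  n_pope <- round(n_bg * 3 / 4)      # 3:1 POPE:POPG
  n_popg <- n_bg - n_pope
  all_res <- unlist(lapply(sites, `[[`, "residue_ids"))
  if (anyDuplicated(all_res))
    stop("planted sites must have pairwise disjoint residue sets",
         call. = FALSE)
  if (length(all_res) && any(all_res >= n_protein_residues))
    stop("site residue ids exceed n_protein_residues", call. = FALSE)
  structure(list(
    n_lipids_by_species = c(POPE = n_pope, POPG = n_popg, CDL = n_min),
    mole_fraction_minority = mole_fraction_minority,
    box = box, n_frames = as.integer(n_frames), frame_dt = frame_dt,
    diffusion_coeff = diffusion_coeff, seed = as.integer(seed),
    sites = sites, n_protein_residues = as.integer(n_protein_residues)
  ), class = "synthetic_config")
}

# Rigid 7-column protein: one backbone bead per residue, columns on a
# circle of radius 10 A, beads spaced 4 A in z, centered on the midplane.
protein_coords <- function(n_res, box, radius = 10, z_spacing = 4) {
  per_col <- ceiling(n_res / 7)
  col_of <- rep(seq_len(7) - 1L, each = per_col)[seq_len(n_res)]
  pos_in_col <- (seq_len(n_res) - 1L) %% per_col
  ang <- 2 * pi * col_of / 7
  z0 <- box[3] / 2
  cbind(box[1] / 2 + radius * cos(ang),
        box[2] / 2 + radius * sin(ang),
        z0 + (pos_in_col - (per_col - 1) / 2) * z_spacing)
}

#' Build the synthetic protein + bilayer system with planted kinetics
#'
#' Generates a full 3D coordinate trajectory: a rigid 7-column
#' transmembrane bead bundle, 3-bead lipids (head + two tail beads) on two
#' leaflets performing 2D periodic Brownian motion, and minority lipids
#' that bind planted sites with the configured Markov rates. While bound, a
#' lipid is held within the site's capture radius; unbound lipids are
#' reflected off an excluded-volume cylinder around the protein whose
#' surface sits between the two contact cutoffs, so planted binding is the
#' only source of contacts (see the methods vignette for what this
#' idealization does and does not test).
#'
#' @param config a [synthetic_config()].
#' @param prefix if non-`NULL`, write `<prefix>.gro` (topology, nm) and
#'   `<prefix>.dcd` (trajectory, Angstrom).
#' @return A list of class `toy_system`: `system` (a `cg_system`), `truth`
#'   (planted site residue sets, bind intervals with times in ns, leaflet
#'   assignment), `config`, and (if written) `files`.
#' @export
build_toy_system <- function(config, prefix = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  box <- config$box
  n_lip <- sum(config$n_lipids_by_species)
  r_excl <- 16                      # excluded-volume cylinder radius (A)
  packing_area <- box[1] * box[2] - pi * r_excl^2
  if (packing_area < 30 * ceiling(n_lip / 2))
    stop("box too small for requested lipid count (packing error)",
         call. = FALSE)
  n_res <- config$n_protein_residues
  n_fr <- config$n_frames
  dt <- config$frame_dt
  T_total <- (n_fr - 1) * dt
  prot <- protein_coords(n_res, box)
  species <- rep(names(config$n_lipids_by_species),
                 config$n_lipids_by_species)
  # alternate leaflets within each species so both leaflets stay 3:1
  leaflet <- unlist(lapply(config$n_lipids_by_species, function(n)
    rep_len(c(1L, -1L), n)), use.names = FALSE)
  plane_z <- box[3] / 2 + leaflet * 17.5
  tail_dir <- -leaflet              # tails point to the midplane
  minority <- which(species == "CDL")
  n_sites <- length(config$sites)

  sim <- with_local_seed(config$seed, {
    # --- initial placement: uniform xy outside the exclusion cylinder
    xy <- matrix(NA_real_, n_lip, 2)
    filled <- 0L
    while (filled < n_lip) {
      cand <- cbind(stats::runif(n_lip, 0, box[1]),
                    stats::runif(n_lip, 0, box[2]))
      r <- sqrt((cand[, 1] - box[1] / 2)^2 + (cand[, 2] - box[2] / 2)^2)
      ok <- which(r >= r_excl)
      take <- ok[seq_len(min(length(ok), n_lip - filled))]
      if (length(take)) {
        xy[(filled + 1):(filled + length(take)), ] <- cand[take, ]
        filled <- filled + length(take)
      }
    }
    # --- planted binding: continuous-time Markov state per minority lipid
    k_on_tot <- if (n_sites) sum(vapply(config$sites, `[[`, 0, "k_on")) else 0
    bind_events <- list()
    state_frames <- matrix(0L, length(minority), n_fr)  # 0 = free, else site
    if (n_sites && length(minority)) {
      k_on_each <- vapply(config$sites, `[[`, 0, "k_on")
      k_off_each <- vapply(config$sites, `[[`, 0, "k_off_true")
      for (mi in seq_along(minority)) {
        t_now <- 0; st <- 0L
        times <- 0; states <- 0L
        while (t_now <= T_total) {
          if (st == 0L) {
            t_now <- t_now + stats::rexp(1, k_on_tot)
            st <- sample.int(n_sites, 1, prob = k_on_each)
          } else {
            t_now <- t_now + stats::rexp(1, k_off_each[st])
            st <- 0L
          }
          times <- c(times, t_now); states <- c(states, st)
        }
        ft <- (seq_len(n_fr) - 1) * dt
        state_frames[mi, ] <- states[findInterval(ft, times)]
        on_idx <- which(states != 0L & times <= T_total)
        if (length(on_idx))
          bind_events[[mi]] <- data.frame(
            lipid = minority[mi], site = states[on_idx],
            t_start = times[on_idx],
            t_end = pmin(c(times, Inf)[on_idx + 1L], T_total))
      }
    }
    # --- site anchor geometry (computed from the rigid protein)
    anchors <- lapply(config$sites, function(s) {
      p <- prot[s$residue_ids + 1L, , drop = FALSE]
      ctr <- colMeans(p)
      ax <- c(box[1] / 2, box[2] / 2)
      u <- ctr[1:2] - ax
      u <- u / sqrt(sum(u^2))
      list(xy = ctr[1:2] + u * 3.5, z = ctr[3])
    })
    # --- propagate and assemble coordinates
    n_bead <- n_res + 3L * n_lip
    coords <- array(NA_real_, c(n_bead, 3, n_fr))
    step_sd <- sqrt(2 * config$diffusion_coeff * dt)
    lip0 <- n_res  # bead offset of first lipid bead
    for (f in seq_len(n_fr)) {
      if (f > 1) {
        xy <- xy + matrix(stats::rnorm(2 * n_lip, 0, step_sd), n_lip, 2)
        xy[, 1] <- xy[, 1] %% box[1]
        xy[, 2] <- xy[, 2] %% box[2]
        dx <- xy[, 1] - box[1] / 2; dy <- xy[, 2] - box[2] / 2
        r <- sqrt(dx^2 + dy^2)
        inside <- r < r_excl
        if (any(inside)) {          # radial reflection off the cylinder
          scale <- (2 * r_excl - r[inside]) / pmax(r[inside], 1e-6)
          xy[inside, 1] <- box[1] / 2 + dx[inside] * scale
          xy[inside, 2] <- box[2] / 2 + dy[inside] * scale
        }
      }
      coords[seq_len(n_res), , f] <- prot
      zj <- stats::rnorm(n_lip, 0, 1.0)
      for (b in 0:2) {              # head, tail1, tail2
        rows <- lip0 + 3L * (seq_len(n_lip) - 1L) + b + 1L
        coords[rows, 1, f] <- xy[, 1]
        coords[rows, 2, f] <- xy[, 2]
        coords[rows, 3, f] <- plane_z + tail_dir * 5 * b + zj
      }
      # bound minority lipids are held at their site anchor
      if (n_sites && length(minority)) {
        bnd <- which(state_frames[, f] != 0L)
        for (mi in bnd) {
          a <- anchors[[state_frames[mi, f]]]
          rows <- lip0 + 3L * (minority[mi] - 1L) + 1:3
          coords[rows, 1, f] <- a$xy[1] + stats::rnorm(3, 0, 0.3)
          coords[rows, 2, f] <- a$xy[2] + stats::rnorm(3, 0, 0.3)
          coords[rows, 3, f] <- a$z + c(-3, 0, 3) + stats::rnorm(3, 0, 0.3)
        }
      }
    }
    list(coords = coords, bind_events = bind_events,
         state_frames = state_frames)
  })

  bead_residue <- c(seq_len(n_res) - 1L,
                    rep(n_res + seq_len(n_lip) - 1L, each = 3L))
  bead_molecule <- c(rep(0L, n_res), rep(seq_len(n_lip), each = 3L))
  bead_name <- c(rep("BB", n_res), rep(c("HD", "T1", "T2"), n_lip))
  system <- cg_system(
    coords = sim$coords, box = box,
    times = (seq_len(n_fr) - 1) * dt,
    bead_residue = bead_residue, bead_molecule = bead_molecule,
    bead_name = bead_name,
    molecule_species = c("protein", species))
  truth <- list(
    site_residues = lapply(config$sites, `[[`, "residue_ids"),
    bind_events = if (length(sim$bind_events))
      do.call(rbind, sim$bind_events) else NULL,
    state_frames = sim$state_frames,
    minority_lipids = minority,       # molecule ids (protein is molecule 0)
    leaflet = ifelse(leaflet > 0, "upper", "lower"))
  out <- structure(list(system = system, truth = truth, config = config),
                   class = "toy_system")
  if (!is.null(prefix)) {
    gro <- paste0(prefix, ".gro"); dcd <- paste0(prefix, ".dcd")
    write_gro(system, gro)
    write_dcd(system$coords, system$box, dcd)
    out$files <- c(topology = gro, trajectory = dcd)
  }
  out
}
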