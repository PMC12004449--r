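# Shared fixtures built in code.

# A flat lattice bilayer: n_side^2 lipids per leaflet on a square lattice,
# head planes at z0 +/- 20, 3 beads per lipid pointing to the midplane.
make_lattice_bilayer <- function(n_side = 8, box = c(80, 80, 100),
                                 n_frames = 1, jitter = 0, seed = 1) {
  spacing <- box[1] / n_side
  g <- expand.grid(x = seq(spacing / 2, box[1] - spacing / 2, by = spacing),
                   y = seq(spacing / 2, box[2] - spacing / 2, by = spacing))
  n <- nrow(g) * 2
  coords <- array(NA_real_, c(n * 3, 3, n_frames))
  bead_res <- integer(n * 3); bead_mol <- integer(n * 3)
  nm <- character(n * 3)
  set.seed(seed)
  k <- 0
  for (leaf in c(1, -1)) for (i in seq_len(nrow(g))) {
    mol <- k %/% 3
    for (b in 0:2) {
      k <- k + 1
      for (f in seq_len(n_frames)) {
        jit <- if (jitter > 0) rnorm(3, 0, jitter) else c(0, 0, 0)
        coords[k, , f] <- c(g$x[i], g$y[i],
                            box[3] / 2 + leaf * 20 - leaf * 5 * b) + jit
      }
      bead_res[k] <- mol; bead_mol[k] <- mol
      nm[k] <- c("HD", "T1", "T2")[b + 1]
    }
  }
  cg_system(coords, box = box, times = seq_len(n_frames) - 1,
            bead_residue = bead_res, bead_molecule = bead_mol,
            bead_name = nm, molecule_species = rep("POPE", n))
}

# A two-site toy config at reduced size (fast enough for many replicates);
# planted residence times default to 1 and 2 us.
two_site_config <- function(seed, n_frames = 2000, frame_dt = 10,
                            n_lipids_total = 64,
                            k_off = c(1e-3, 5e-4), k_on = 1e-4) {
  synthetic_config(
    n_lipids_total = n_lipids_total, mole_fraction_minority = 0.10,
    n_frames = n_frames, frame_dt = frame_dt, seed = seed,
    sites = list(planted_site(c(2, 3, 4, 5), k_on, k_off[1]),
                 planted_site(c(32, 33, 34, 35), k_on, k_off[2])))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Random occupancy series with tunable density and persistence.
random_series <- function(n_lipids, n_frames, seed, p_on = 0.2,
                          frame_dt = 1) {
  set.seed(seed)
  occ <- array(FALSE, c(n_lipids, 1, n_frames))
  for (i in seq_len(n_lipids)) {
    # a sticky two-state chain gives realistic run structure
    p_stay <- runif(1, 0.6, 0.98)
    x <- logical(n_frames)
    x[1] <- runif(1) < p_on
    for (f in 2:n_frames)
      x[f] <- if (x[f - 1]) runif(1) < p_stay else runif(1) < p_on / 4
    occ[i, 1, ] <- x
  }
  contact_series(occ, frame_dt = frame_dt)
}
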