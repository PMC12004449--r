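#' Build the residue co-contact network
#'
#' Nodes are the protein residues that ever make contact; the edge weight
#' between residues r and s is the number of (frame, lipid) pairs in which
#' the same lipid molecule contacts both residues simultaneously. Heavy
#' cliques in this network are residues repeatedly bridged by one bound
#' lipid — the signature of a binding site.
#'
#' @param series a `contact_series`.
#' @return An object of class `residue_graph`: `residues` (0-based ids)
#'   and `weights` (symmetric matrix, zero diagonal).
#' @export
build_residue_graph <- function(series) {
  occ <- series$occupancy
  d <- dim(occ)
  touched <- which(apply(occ, 2, any))
  if (length(touched) == 0)
    stop("empty contact series: no contacted residues", call. = FALSE)
  W <- matrix(0, length(touched), length(touched))
  for (i in seq_len(d[1])) {
    M <- matrix(occ[i, touched, ], length(touched), d[3])
    storage.mode(M) <- "numeric"
    W <- W + M %*% t(M)
  }
  diag(W) <- 0
  structure(list(residues = series$residue_ids[touched], weights = W),
            class = "residue_graph")
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$residue <- graph$residues
  g
}

#' Partition the residue network into binding sites (Louvain)
#'
#' Runs Louvain modularity optimization on the weighted co-contact
#' network, then merges communities smaller than `min_size` into the
#' community they share the most edge weight with (an isolated small
#' community with no outside edges is left as is). Deterministic for a
#' fixed seed.
#'
#' @param graph a `residue_graph`.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @param min_size communities below this size are merged (default 3).
#' @return list of integer vectors of 0-based residue ids (a partition of
#'   the contacted residues).
#' @export
louvain_partition <- function(graph, resolution = 1.0, seed = 1,
                              min_size = 3) {
  g <- as_igraph(graph)
  comm <- with_local_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  member <- igraph::membership(comm)
  member <- merge_small_communities(graph$weights, as.integer(member),
                                    min_size)
  unname(split(graph$residues, member))
}

merge_small_communities <- function(W, member, min_size) {
  repeat {
    sizes <- table(member)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) == 1) break
    changed <- FALSE
    for (cid in small) {
      nodes <- which(member == cid)
      other <- member != cid
      if (!any(other)) next
      w_to <- tapply(colSums(W[nodes, , drop = FALSE])[other], member[other],
                     sum)
      if (all(w_to == 0)) next      # isolated: leave it
      target <- names(w_to)[which.max(w_to)]
      member[nodes] <- as.integer(target)
      changed <- TRUE
      break                          # recompute sizes after each merge
    }
    if (!changed) break
  }
  member
}

#' Kinetics of a binding site (union occupancy)
#'
#' A lipid is "at the site" while in contact with any residue of the site,
#' so the site occupancy of a lipid is the union of its per-residue
#' occupancies; interleaved contacts with different member residues merge
#' into single site events. Survival function and biexponential fit are
#' computed on that union series.
#'
#' @param site_residues 0-based residue ids of the site.
#' @param series a `contact_series`.
#' @param t_max_frames fitting lag range (frames), default as in
#'   [per_residue_residence_times()].
#' @param seed fit multi-start seed.
#' @return list: `fit` (a `kinetic_fit`), `events` (site event table),
#'   `occupancy_fraction` (fraction of frames with >= 1 lipid at the
#'   site).
#' @export
site_kinetics <- function(site_residues, series, t_max_frames = NULL,
                          seed = 1) {
  if (length(site_residues) == 0)
    stop("site must contain at least one residue", call. = FALSE)
  cols <- match(site_residues, series$residue_ids)
  if (anyNA(cols)) stop("site residues not present in the contact series",
                        call. = FALSE)
  occ <- series$occupancy[, cols, , drop = FALSE]
  d <- dim(occ)
  union_occ <- array(apply(occ, c(1, 3), any), c(d[1], 1, d[3]))
  union_series <- contact_series(union_occ, frame_dt = series$frame_dt,
                                 lipid_ids = series$lipid_ids,
                                 residue_ids = 0L)
  ev <- events_from_series(union_series)
  if (nrow(ev) == 0)
    stop("no contacts at this site (no binding)", call. = FALSE)
  nfr <- d[3]
  tm <- if (is.null(t_max_frames)) default_t_max(mean(ev$length), nfr)
        else t_max_frames
  curve <- survival_function(ev, n_frames = nfr, t_max_frames = tm,
                             frame_dt = series$frame_dt)
  list(fit = fit_biexponential(curve, seed = seed), events = ev,
       occupancy_fraction = mean(apply(union_occ[, 1, , drop = FALSE], 3,
                                       any)))
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Approximate surface area of a binding site
#'
#' Shrake-Rupley-style solvent-accessible surface area on coarse-grained
#' beads: each site bead is inflated by the probe radius, sampled with a
#' deterministic golden-spiral point set, and sample points falling inside
#' any other inflated bead of the protein are discarded. Averaged over a
#' subsample of frames (for a rigid protein one frame suffices). Defaults
#' are a typical CG bead van der Waals radius (2.64 Angstrom) and a water
#' probe (1.85 Angstrom).
#'
#' @param site_residues 0-based residue ids of the site.
#' @param system a `cg_system`.
#' @param probe_radius probe radius (Angstrom).
#' @param bead_radius bead radius (Angstrom).
#' @param n_points sample points per bead.
#' @param frames frame indices to average over (default up to 5, evenly
#'   spaced).
#' @param protein_species species treated as the protein surface.
#' @return Area in nm^2.
#' @export
site_surface_area <- function(site_residues, system, probe_radius = 1.85,
                              bead_radius = 2.64, n_points = 960,
                              frames = NULL,
                              protein_species = "protein") {
  prot_beads <- beads_of_species(system, protein_species)
  site_beads <- prot_beads[system$bead_residue[prot_beads] %in% site_residues]
  if (length(site_beads) == 0)
    stop("site residues not present in system", call. = FALSE)
  if (is.null(frames))
    frames <- unique(round(seq(1, n_frames(system), length.out = 5)))
  R <- bead_radius + probe_radius
  pts <- sphere_points(n_points) * R
  area_frames <- vapply(frames, function(f) {
    centers <- system$coords[prot_beads, , f, drop = FALSE][, , 1]
    if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
    # drop duplicate centers so coincident beads count once
    keep <- !duplicated(round(centers, 6))
    centers <- centers[keep, , drop = FALSE]
    kept_beads <- prot_beads[keep]
    is_site <- kept_beads %in% site_beads
    total <- 0
    for (b in which(is_site)) {
      p <- sweep(pts, 2, centers[b, ], "+")
      occluded <- rep(FALSE, n_points)
      for (o in seq_len(nrow(centers))) {
        if (o == b) next
        d2 <- (p[, 1] - centers[o, 1])^2 + (p[, 2] - centers[o, 2])^2 +
          (p[, 3] - centers[o, 3])^2
        occluded <- occluded | (d2 < R^2 * (1 - 1e-9))
        if (all(occluded)) break
      }
      total <- total + mean(!occluded) * 4 * pi * R^2
    }
    total
  }, numeric(1))
  mean(area_frames) / 100   # A^2 -> nm^2
}

#' Full binding-site table
#'
#' Partitions the contacted residues into sites, computes per-site
#' kinetics, occupancy and surface area, and ranks sites by descending
#' total occupancy so the labels BS0, BS1, ... are stable across runs.
#'
#' @param series a `contact_series`.
#' @param system the `cg_system` the series came from (for surface areas);
#'   `NULL` skips areas.
#' @param resolution,seed,min_size passed to [louvain_partition()].
#' @return data.frame, one row per site: `site_id`, `n_residues`,
#'   `residues` (comma-separated, 1-based), `time_us`, `r_squared`,
#'   `area_nm2`, `occupancy_fraction`, `n_events`.
#' @export
binding_site_table <- function(series, system = NULL, resolution = 1.0,
                               seed = 1, min_size = 3) {
  graph <- build_residue_graph(series)
  parts <- louvain_partition(graph, resolution = resolution, seed = seed,
                             min_size = min_size)
  info <- lapply(parts, function(res) {
    sk <- site_kinetics(res, series, seed = seed)
    area <- if (is.null(system)) NA_real_ else
      site_surface_area(res, system)
    list(res = res, sk = sk, area = area)
  })
  occ <- vapply(info, function(x) x$sk$occupancy_fraction, numeric(1))
  info <- info[order(-occ)]
  rows <- lapply(seq_along(info), function(i) {
    x <- info[[i]]
    data.frame(
      site_id = paste0("BS", i - 1L),
      n_residues = length(x$res),
      residues = paste(sort(x$res) + 1L, collapse = ","),
      time_us = x$sk$fit$residence_time,
      r_squared = x$sk$fit$r_squared,
      area_nm2 = x$area,
      occupancy_fraction = x$sk$occupancy_fraction,
      n_events = nrow(x$sk$events))
  })
  do.call(rbind, rows)
}
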