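test_that("co-contact weights match their definition and a triple-loop oracle", {
  # one lipid touching residues 10 and 11 simultaneously for 50 frames
  occ <- array(FALSE, c(1, 2, 80))
  occ[1, 1, 1:50] <- TRUE
  occ[1, 2, 1:50] <- TRUE
  series <- contact_series(occ, 1, residue_ids = c(10L, 11L))
  g <- build_residue_graph(series)
  expect_equal(g$weights[1, 2], 50)

  # never co-contacted: no edge
  occ2 <- array(FALSE, c(1, 2, 80))
  occ2[1, 1, 1:10] <- TRUE
  occ2[1, 2, 30:40] <- TRUE
  g2 <- build_residue_graph(contact_series(occ2, 1))
  expect_equal(g2$weights[1, 2], 0)

  # random series vs brute force over (lipid, frame, residue pair)
  set.seed(14)
  occ3 <- array(runif(5 * 4 * 60) < 0.3, c(5, 4, 60))
  g3 <- build_residue_graph(contact_series(occ3, 1))
  for (r in 1:3) for (s in (r + 1):4) {
    w <- 0
    for (l in 1:5) for (f in 1:60)
      w <- w + (occ3[l, r, f] && occ3[l, s, f])
    ri <- match(r - 1, g3$residues); si <- match(s - 1, g3$residues)
    expect_equal(g3$weights[ri, si], w)
    expect_equal(g3$weights[si, ri], w)
  }
  expect_true(all(diag(g3$weights) == 0))
})

test_that("Louvain separates disconnected cliques and handles singletons", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 3; W[6:10, 6:10] <- 3
  diag(W) <- 0
  graph <- structure(list(residues = 0:9, weights = W),
                     class = "residue_graph")
  parts <- louvain_partition(graph, seed = 1)
  expect_length(parts, 2)
  expect_setequal(lapply(parts, sort), list(0:4, 5:9))

  single <- structure(list(residues = 42L,
                           weights = matrix(0, 1, 1)),
                      class = "residue_graph")
  expect_equal(louvain_partition(single, min_size = 1)[[1]], 42L)
})

test_that("Louvain recovers planted partitions on noisy graphs", {
  recover <- function(seed) {
    set.seed(seed)
    n <- 40
    truth <- rep(1:2, each = 20)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (truth[i] == truth[j]) 0.9 else 0.05
      if (runif(1) < p) W[i, j] <- W[j, i] <- 1
    }
    graph <- structure(list(residues = 0:(n - 1), weights = W),
                       class = "residue_graph")
    parts <- louvain_partition(graph, seed = seed)
    length(parts) == 2 &&
      min(sapply(parts, function(p)
        max(jaccard(p, 0:19), jaccard(p, 20:39)))) == 1
  }
  hits <- sum(vapply(1:30, recover, logical(1)))
  expect_gte(hits, 29)
})

test_that("partition covers the contacted residues exactly once", {
  cfg <- two_site_config(seed = 15)
  toy <- build_toy_system(cfg)
  series <- detect_contacts(toy$system, cg_selection(lipid_species = "CDL"))
  graph <- build_residue_graph(series)
  parts <- louvain_partition(graph, seed = 1)
  all_res <- sort(unlist(parts))
  expect_equal(all_res, sort(graph$residues))      # disjoint and covering
  # returned modularity beats the trivial one-community partition
  g <- igraph::graph_from_adjacency_matrix(graph$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  member <- integer(length(graph$residues))
  for (i in seq_along(parts))
    member[match(parts[[i]], graph$residues)] <- i
  q_parts <- igraph::modularity(g, member, weights = igraph::E(g)$weight)
  q_trivial <- igraph::modularity(g, rep(1, length(graph$residues)),
                                  weights = igraph::E(g)$weight)
  expect_gte(q_parts, q_trivial)
})

test_that("site kinetics reduce to per-residue kinetics for one residue", {
  cs <- simulate_contact_series(0.02, 0.02, 5000, n_lipids = 10, seed = 16)
  sk <- site_kinetics(0L, cs)
  res <- per_residue_residence_times(cs)
  expect_equal(sk$fit$residence_time, res$time_us[1])
  # site event count bound: union merges, never splits
  ev_res <- events_from_series(cs)
  expect_lte(nrow(sk$events), nrow(ev_res))
})

test_that("union occupancy merges interleaved residue contacts", {
  occ <- array(FALSE, c(1, 2, 20))
  occ[1, 1, c(1:4, 9:12)] <- TRUE
  occ[1, 2, 3:10] <- TRUE
  series <- contact_series(occ, 1, residue_ids = 0:1)
  sk <- site_kinetics(0:1, series, t_max_frames = 10)
  # interval-union oracle
  union_frames <- sort(unique(c(1:4, 9:12, 3:10)))
  r <- rle(seq_len(20) %in% union_frames)
  expect_equal(nrow(sk$events), sum(r$values))
  expect_equal(sum(sk$events$length), length(union_frames))
})

test_that("planted two-site systems are recovered with high Jaccard", {
  cfg <- two_site_config(seed = 18)
  toy <- build_toy_system(cfg)
  series <- detect_contacts(toy$system, cg_selection(lipid_species = "CDL"))
  tab <- binding_site_table(series, toy$system)
  expect_equal(nrow(tab), 2)
  found <- lapply(strsplit(tab$residues, ","),
                  function(x) as.integer(x) - 1L)
  truth <- toy$truth$site_residues
  j <- sapply(truth, function(tr)
    max(sapply(found, function(f) jaccard(f, tr))))
  expect_true(all(j >= 0.8))
})

test_that("site residence time recovers planted kinetics (union series)", {
  # a 4-residue site bound by 12 lipids with tau_true = 2 us; residue 0 is
  # always contacted while bound, the others flicker, so the union series
  # carries the planted dwell structure
  n_fr <- 4000
  occ <- array(FALSE, c(12, 4, n_fr))
  set.seed(33)
  for (l in 1:12) {
    cs <- simulate_contact_series(k_off = 5e-4, k_on_eff = 5e-4,
                                  n_frames = n_fr, frame_dt = 10,
                                  n_lipids = 1, seed = 400 + l)
    bound <- cs$occupancy[1, 1, ]
    occ[l, 1, ] <- bound
    for (r in 2:4) occ[l, r, ] <- bound & (runif(n_fr) < 0.8)
  }
  series <- contact_series(occ, frame_dt = 10, residue_ids = 0:3)
  sk <- site_kinetics(0:3, series)
  expect_true(sk$fit$converged)
  expect_lt(abs(sk$fit$residence_time - 2) / 2, 0.25)
  # union events match the always-contacted residue's events exactly
  ev0 <- events_from_series(contact_series(
    array(occ[, 1, ], c(12, 1, n_fr)), 10))
  expect_equal(nrow(sk$events), nrow(ev0))
})

test_that("bead surface areas match closed forms and a Monte-Carlo oracle", {
  R <- 2.64 + 1.85
  one <- cg_system(array(c(0, 0, 0), c(1, 3, 1)), c(100, 100, 100), 0,
                   0L, 0L, "BB", "protein")
  expect_equal(site_surface_area(0L, one, frames = 1),
               4 * pi * R^2 / 100, tolerance = 1e-6)
  # two fully overlapping beads count once
  two <- cg_system(array(0, c(2, 3, 1)), c(100, 100, 100), 0,
                   c(0L, 0L), c(0L, 0L), c("BB", "BB"), "protein")
  expect_equal(site_surface_area(0L, two, frames = 1),
               4 * pi * R^2 / 100, tolerance = 1e-6)

  # random clusters vs an independent random-direction sampler
  set.seed(19)
  for (rep in 1:3) {
    n <- 6
    centers <- matrix(runif(3 * n, 0, 6), n, 3)
    sys <- cg_system(array(centers, c(n, 3, 1)), c(100, 100, 100), 0,
                     seq_len(n) - 1L, rep(0L, n), rep("BB", n), "protein")
    a <- site_surface_area(seq_len(n) - 1L, sys, frames = 1,
                           n_points = 4000)
    mc <- 0
    for (b in seq_len(n)) {
      dirs <- matrix(rnorm(3 * 20000), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- sweep(dirs * R, 2, centers[b, ], "+")
      excl <- rep(FALSE, nrow(pts))
      for (o in seq_len(n)) {
        if (o == b) next
        d2 <- rowSums(sweep(pts, 2, centers[o, ])^2)
        excl <- excl | d2 < R^2 * (1 - 1e-9)
      }
      mc <- mc + mean(!excl) * 4 * pi * R^2
    }
    expect_equal(a, mc / 100, tolerance = 0.02)
  }
})
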