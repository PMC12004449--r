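test_that("full occupancy gives a flat survival function", {
  occ <- contact_series(array(TRUE, c(1, 1, 100)), 1)
  ev <- events_from_series(occ)
  sc <- survival_function(ev, n_frames = 100, t_max_frames = 50)
  expect_true(all(sc$sigma == 1))
})

test_that("survival of Markov contacts approaches exp(-k_off t)", {
  cs <- simulate_contact_series(k_off = 0.01, k_on_eff = 0.01,
                                n_frames = 5e4, n_lipids = 20, seed = 12)
  ev <- events_from_series(cs)
  sc <- survival_function(ev, n_frames = 5e4, t_max_frames = 200)
  expect_lt(max(abs(sc$sigma - exp(-0.01 * sc$lag_frames))), 0.05)
})

test_that("fast survival evaluation equals the direct definition", {
  for (seed in 1:10) {
    cs <- random_series(10, 400, seed = seed)
    ev <- events_from_series(cs)
    if (nrow(ev) == 0) next
    a <- survival_function(ev, 400, 150, frame_dt = cs$frame_dt)
    b <- survival_function_direct(cs, 150)
    expect_lt(max(abs(a$sigma - b$sigma) / pmax(abs(b$sigma), 1e-300)),
              1e-12)
    expect_equal(a$n_contacts, b$n_contacts)
  }
})

test_that("survival errors cleanly with zero contacts", {
  empty <- contact_series(array(FALSE, c(2, 1, 50)), 1)
  expect_error(survival_function(events_from_series(empty), 50, 10),
               "no binding")
  expect_error(survival_function_direct(empty, 10), "no binding")
})

test_that("noiseless biexponential curves are recovered exactly", {
  t_us <- seq(0, 10, by = 0.02)
  curve <- structure(list(
    lag_frames = seq_along(t_us) - 1, lag_times = t_us * 1000,
    sigma = 0.7 * exp(-0.5 * t_us) + 0.3 * exp(-5 * t_us),
    n_contacts = 100L, T_total = length(t_us), frame_dt = 20,
    mean_dwell_frames = NA_real_), class = "survival_curve")
  f <- fit_biexponential(curve)
  expect_true(f$converged)
  expect_equal(f$amplitude_slow, 0.7, tolerance = 1e-6)
  expect_equal(f$rate_slow, 0.5, tolerance = 1e-6)
  expect_equal(f$amplitude_fast, 0.3, tolerance = 1e-6)
  expect_equal(f$rate_fast, 5, tolerance = 1e-6)
  expect_equal(f$residence_time, 2, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)
})

test_that("a pure single exponential yields tau = 1/k within 1%", {
  t_us <- seq(0, 4, by = 0.01)
  for (k in c(0.5, 2)) {
    curve <- structure(list(
      lag_frames = seq_along(t_us) - 1, lag_times = t_us * 1000,
      sigma = exp(-k * t_us), n_contacts = 50L, T_total = length(t_us),
      frame_dt = 10, mean_dwell_frames = NA_real_),
      class = "survival_curve")
    f <- fit_biexponential(curve)
    expect_true(f$converged)
    expect_lt(abs(f$residence_time - 1 / k) / (1 / k), 0.01)
  }
})

test_that("residence time is reported as 1/k_off in microseconds", {
  # reporting convention: a slow rate of 0.2632/us is a 3.8 us residence
  t_us <- seq(0, 15, by = 0.05)
  curve <- structure(list(
    lag_frames = seq_along(t_us) - 1, lag_times = t_us * 1000,
    sigma = 0.8 * exp(-0.2632 * t_us) + 0.2 * exp(-3 * t_us),
    n_contacts = 10L, T_total = length(t_us), frame_dt = 50,
    mean_dwell_frames = NA_real_), class = "survival_curve")
  f <- fit_biexponential(curve)
  expect_equal(f$rate_slow, 0.2632, tolerance = 1e-4)
  expect_equal(f$residence_time, 1 / f$rate_slow)   # exact identity
  expect_equal(f$residence_time, 3.8, tolerance = 1e-3)
})

test_that("sigma is invariant to lipid relabeling and tau to time units", {
  cs <- simulate_contact_series(0.02, 0.02, 5000, n_lipids = 8, seed = 13)
  ev <- events_from_series(cs)
  sc1 <- survival_function(ev, 5000, 400)
  ev_shuf <- ev
  perm <- c(8, 3, 1, 2, 7, 5, 6, 4)
  ev_shuf$lipid_id <- perm[ev_shuf$lipid_id]
  sc2 <- survival_function(ev_shuf, 5000, 400)
  expect_identical(sc1$sigma, sc2$sigma)

  # fitting the same curve with ns-scaled vs us-scaled lag times
  mk <- function(dt_ns) structure(list(
    lag_frames = sc1$lag_frames, lag_times = sc1$lag_frames * dt_ns,
    sigma = sc1$sigma, n_contacts = sc1$n_contacts, T_total = 5000,
    frame_dt = dt_ns, mean_dwell_frames = mean(ev$length)),
    class = "survival_curve")
  f1 <- fit_biexponential(mk(1))      # frame = 1 ns
  f10 <- fit_biexponential(mk(10))    # frame = 10 ns
  expect_equal(f10$residence_time / f1$residence_time, 10,
               tolerance = 1e-3)
})

test_that("doubling k_off halves the recovered residence time", {
  tau <- sapply(c(0.01, 0.02), function(k) {
    cs <- simulate_contact_series(k, 0.02, 4e4, n_lipids = 15, seed = 21)
    ev <- events_from_series(cs)
    sc <- survival_function(ev, 4e4, 1000)
    fit_biexponential(sc)$residence_time
  })
  expect_equal(tau[1] / tau[2], 2, tolerance = 0.25)
})

test_that("per-residue tables pool lipids and omit sparse residues", {
  # residues 0 and 1 share planted kinetics; residue 2 is never contacted
  set.seed(30)
  occ <- array(FALSE, c(6, 3, 4000))
  for (r in 1:2) {
    cs <- simulate_contact_series(0.02, 0.02, 4000, n_lipids = 6,
                                  seed = 30 + r)
    occ[, r, ] <- cs$occupancy[, 1, ]
  }
  series <- contact_series(occ, frame_dt = 10)
  res <- per_residue_residence_times(series)
  expect_setequal(res$residue, c(1, 2))  # 1-based report; residue 3 missing
  # identical generators: recovered taus agree within sampling error
  expect_lt(abs(diff(res$time_us)) / mean(res$time_us), 0.3)
  # true tau = 50 frames * 10 ns = 0.5 us
  expect_true(all(abs(res$time_us - 0.5) / 0.5 < 0.25))
})
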