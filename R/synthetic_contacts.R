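#' Simulate raw binary contact series from a two-state Markov process
#'
#' Each lipid channel is an alternating bound/unbound telegraph process in
#' continuous time: unbound dwells are Exponential(rate = `k_on_eff`) and
#' bound dwells Exponential(rate = `k_off`). The process is then sampled at
#' the frame times (instantaneous sampling at `f * frame_dt`), so a dwell
#' shorter than one frame can vanish — the same undersampling bias a saved
#' MD trajectory has.
#'
#' Rates and `frame_dt` share one time unit (use ns throughout, or /frame
#' with `frame_dt = 1`).
#'
#' @param k_off dissociation rate (per time unit), `> 0`.
#' @param k_on_eff effective association rate (per time unit), `> 0`.
#' @param n_frames number of frames, `>= 2`.
#' @param frame_dt time per frame.
#' @param n_lipids number of independent lipid channels.
#' @param seed integer seed; fixed seed gives a bit-identical series.
#' @param start_state `"stationary"` draws the initial state from the
#'   equilibrium occupancy `k_on/(k_on + k_off)`; `"bound"`/`"unbound"`
#'   force it.
#' @return A `contact_series` (`n_lipids x 1 x n_frames`) with the exact
#'   continuous-time bound dwells attached as attribute `"dwell_times"`
#'   (completed dwells only, for distributional checks).
#' @export
simulate_contact_series <- function(k_off, k_on_eff, n_frames, frame_dt = 1,
                                    n_lipids = 1, seed = 1,
                                    start_state = c("stationary", "bound",
                                                    "unbound")) {
  if (k_off <= 0 || k_on_eff <= 0)
    stop("rates must be positive", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (n_lipids < 1) stop("n_lipids must be >= 1", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be positive", call. = FALSE)
  start_state <- match.arg(start_state)
  T_total <- (n_frames - 1) * frame_dt
  occ <- array(FALSE, c(n_lipids, 1, n_frames))
  dwells <- vector("list", n_lipids)
  with_local_seed(seed, {
    for (i in seq_len(n_lipids)) {
      bound <- switch(start_state,
                      stationary = stats::runif(1) <
                        k_on_eff / (k_on_eff + k_off),
                      bound = TRUE,
                      unbound = FALSE)
      t_now <- 0
      switch_times <- numeric(0)
      states <- logical(0)
      # dwell sequence in continuous time until the trajectory ends
      st <- bound
      while (t_now <= T_total) {
        states <- c(states, st)
        switch_times <- c(switch_times, t_now)
        t_now <- t_now + stats::rexp(1, if (st) k_off else k_on_eff)
        st <- !st
      }
      # completed bound dwells (exclude the final, censored interval)
      n_int <- length(switch_times)
      if (n_int > 1) {
        len <- diff(c(switch_times, t_now))[seq_len(n_int - 1)]
        dwells[[i]] <- len[states[seq_len(n_int - 1)]]
      }
      # instantaneous sampling at frame times
      ft <- (seq_len(n_frames) - 1) * frame_dt
      idx <- findInterval(ft, switch_times)
      occ[i, 1, ] <- states[idx]
    }
  })
  out <- contact_series(occ, frame_dt = frame_dt)
  attr(out, "dwell_times") <- unlist(dwells)
  out
}
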