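#' Contact occupancy container
#'
#' Boolean occupancy over (lipid molecule, protein residue, frame), either
#' detected from coordinates under the dual-cutoff scheme or generated
#' directly by the two-state Markov simulator.
#'
#' @param occupancy logical array `n_lipids x n_residues x n_frames`.
#' @param frame_dt time per frame (ns).
#' @param lipid_ids identifiers for the lipid molecules (rows).
#' @param residue_ids 0-based residue indices (columns).
#' @param cutoff_lower,cutoff_upper the dual cutoffs used (Angstrom), `NA`
#'   for simulated series.
#' @return An object of class `contact_series`.
#' @export
contact_series <- function(occupancy, frame_dt, lipid_ids = NULL,
                           residue_ids = NULL, cutoff_lower = NA_real_,
                           cutoff_upper = NA_real_) {
  if (length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3-d array (lipid x residue x frame)",
         call. = FALSE)
  if (!is.na(cutoff_lower) && !is.na(cutoff_upper) &&
      cutoff_lower > cutoff_upper)
    stop("cutoff_lower must be <= cutoff_upper", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be positive", call. = FALSE)
  d <- dim(occupancy)
  structure(list(
    occupancy = occupancy,
    frame_dt = frame_dt,
    lipid_ids = if (is.null(lipid_ids)) seq_len(d[1]) else lipid_ids,
    residue_ids = if (is.null(residue_ids)) seq_len(d[2]) - 1L else
      as.integer(residue_ids),
    cutoff_lower = cutoff_lower,
    cutoff_upper = cutoff_upper
  ), class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "contact_series: %d lipids x %d residues x %d frames (dt = %g ns), %.2f%% occupied\n",
    d[1], d[2], d[3], x$frame_dt, 100 * mean(x$occupancy)))
  invisible(x)
}

#' Extract maximal contact events from a contact series
#'
#' A contact event is a maximal run of consecutive occupied frames for one
#' (lipid, residue) pair, reported as a half-open frame interval
#' `[start_frame, end_frame)`. An event still open at the final frame is
#' flagged as right-censored: its observed length is a lower bound on the
#' true dwell.
#'
#' @param series a `contact_series`.
#' @return data.frame with columns `lipid_id`, `residue` (0-based),
#'   `start_frame`, `end_frame`, `length` (frames), `censored`.
#' @export
events_from_series <- function(series) {
  occ <- series$occupancy
  d <- dim(occ)
  out <- vector("list", d[1] * d[2])
  k <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      r <- rle(as.logical(occ[i, j, ]))
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      sel <- r$values
      k <- k + 1L
      out[[k]] <- data.frame(
        lipid_id = series$lipid_ids[i],
        residue = series$residue_ids[j],
        start_frame = starts[sel],
        end_frame = ends[sel],
        censored = ends[sel] == d[3]
      )
    }
  }
  if (k == 0L)
    return(data.frame(lipid_id = integer(), residue = integer(),
                      start_frame = integer(), end_frame = integer(),
                      censored = logical(), length = integer()))
  ev <- do.call(rbind, out[seq_len(k)])
  ev$length <- ev$end_frame - ev$start_frame
  rownames(ev) <- NULL
  ev
}
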