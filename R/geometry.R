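#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between points under periodic boundary conditions,
#' taking the nearest periodic image along each axis independently (valid
#' for orthorhombic boxes only).
#'
#' @param a,b numeric vectors of length 3, or matrices with 3 columns
#'   (rows are paired).
#' @param box length-3 vector of box edge lengths.
#' @return Numeric vector of distances.
#' @export
minimum_image_distance <- function(a, b, box) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- abs(a - b)
  d <- sweep(d, 2, box, function(x, L) pmin(x, L - x))
  sqrt(rowSums(d * d))
}

# Squared minimum-image distances between every row of A (n x 3) and every
# row of B (m x 3); returns an n x m matrix. All-pairs, vectorized per axis.
min_image_dist2_matrix <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- abs(outer(A[, k], B[, k], "-"))
    d <- pmin(d, box[k] - d)
    out <- out + d * d
  }
  out
}

# Minimum over groups of rows: collapse an n x m matrix to g x m by taking
# the min over rows sharing a group id (1-based, contiguous not required).
group_min_rows <- function(mat, groups) {
  # fast path: contiguous equal-sized groups (e.g. k beads per molecule)
  r <- rle(groups)
  if (!anyDuplicated(r$values) && !is.unsorted(r$values) &&
      length(unique(r$lengths)) == 1L) {
    k <- r$lengths[1]
    if (k == 1L) return(mat)
    g <- length(r$values)
    a <- array(mat, c(k, g, ncol(mat)))
    out <- a[1, , , drop = TRUE]
    if (g == 1L || ncol(mat) == 1L) out <- matrix(out, g, ncol(mat))
    for (j in 2:k) {
      layer <- a[j, , , drop = TRUE]
      if (g == 1L || ncol(mat) == 1L) layer <- matrix(layer, g, ncol(mat))
      out <- pmin(out, layer)
    }
    return(out)
  }
  idx <- split(seq_len(nrow(mat)), groups)
  out <- matrix(NA_real_, length(idx), ncol(mat))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    out[i, ] <- if (length(rows) == 1L) mat[rows, ] else
      do.call(pmin, lapply(rows, function(r) mat[r, ]))
  }
  rownames(out) <- names(idx)
  out
}
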