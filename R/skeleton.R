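# Mask morphology and centreline extraction.

# Shift a logical array by one step along axis `ax` (direction +-1),
# padding with FALSE.
shift_logical <- function(m, ax, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1L)
  } else {
    idx_dst[[ax]] <- 1:(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax]
  }
  out[matrix_index(idx_dst, d)] <- m[matrix_index(idx_src, d)]
  out
}

# Build a flat index vector for a rectangular sub-block given per-axis indices.
matrix_index <- function(idx, d) {
  g <- as.matrix(expand.grid(idx))
  if (length(d) == 2L) (g[, 2] - 1L) * d[1] + g[, 1]
  else ((g[, 3] - 1L) * d[2] + (g[, 2] - 1L)) * d[1] + g[, 1]
}

#' Morphological erosion with a cross structuring element
#'
#' 3x3 (2D) or 3x3x3 (3D) cross; `iterations = 0` is the identity. Used for
#' the "twice eroded" skeleton visualization; not part of the quantitative
#' chain.
#'
#' @param mask logical matrix or 3D logical array.
#' @param iterations number of erosions (>= 0).
#' @return Eroded mask of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(is.logical(mask), iterations >= 0)
  if (iterations == 0L) return(mask)
  d <- dim(mask)
  for (i in seq_len(iterations)) {
    res <- mask
    for (ax in seq_along(d)) {
      res <- res & shift_logical(mask, ax, 1L) & shift_logical(mask, ax, -1L)
    }
    mask <- res
  }
  mask
}

#' Skeletonize a 2D mask
#'
#' Zhang-Suen thinning to a 1-pixel-wide, 8-connected centreline;
#' homotopy-preserving and idempotent on its own output.
#'
#' @param mask logical matrix.
#' @return Logical matrix skeleton.
#' @export
skeletonize_2d <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .thin_cleanup_cpp(.thin2d_cpp(mask))
}

#' Thin a 3D voxel set to unit-width curves
#'
#' Sequential simple-point removal (26-connected foreground, 6-connected
#' background), preserving curve endpoints.
#'
#' @param vol logical 3D array.
#' @return Thinned logical 3D array.
#' @export
skeletonize_3d <- function(vol) {
  stopifnot(is.logical(vol), length(dim(vol)) == 3L)
  .thin3d_cpp(vol, dim(vol))
}
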