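# 3D ridge detection: bright curvilinear structures are loci where the two
# Hessian eigenvalues across the tube are strongly negative while the third
# (along the axis) is near zero. Candidate voxels pass an eigenvalue
# threshold with hysteresis, survive non-maximum suppression across the
# ridge normal plane, and are thinned to unit-width curves.

# Separable 3D Gaussian-derivative convolution; orders (or, oc, oz) in {0,1,2}.
conv3 <- function(vol, sigma, orders, z_sigma = sigma) {
  kr <- gauss_kernel1d(sigma, orders[1])
  kc <- gauss_kernel1d(sigma, orders[2])
  kz <- gauss_kernel1d(z_sigma, orders[3])
  out <- vol
  for (k in seq_len(dim(vol)[3]))
    out[, , k] <- conv_sep(vol[, , k], kr, kc)
  conv_z(out, kz)
}

# Eigenvalues of symmetric 3x3 matrices, vectorized (trigonometric method).
# Inputs are the six unique components; returns a list l1 <= l2 <= l3.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 1e-30
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e3 <- q[nz] + 2 * p[nz] * cos(phi)
    e1 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    l1[nz] <- e1; l2[nz] <- e2; l3[nz] <- e3
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' 3D ridge detection
#'
#' Extracts the 3D centreline network of bright tubular structures from a
#' z-stack, allowing junctions that occur between z-planes to be separated
#' (a 2D projection conflates fibres crossing at different depths). Ridge
#' strength is `sqrt(l1 * l2)` of the scale-normalized Hessian where both
#' cross-axis eigenvalues `l1 <= l2 < 0`; voxels above `low` (fraction of
#' the maximum response) that connect to a voxel above `high` are kept
#' (hysteresis), non-maximal voxels across the ridge normal plane are
#' suppressed, and the result is thinned with [skeletonize_3d()].
#'
#' @param stack an [image_stack()] with >= 3 slices.
#' @param sigma Gaussian derivative scale in px (about the fibre radius).
#' @param low,high hysteresis thresholds as fractions of the peak response.
#' @return Logical 3D array (rows x cols x slices) of centreline voxels.
#' @export
ridge_detect_3d <- function(stack, sigma = 2, low = 0.1, high = 0.25) {
  stopifnot(inherits(stack, "ImageStack"))
  vol <- stack$voxels
  nz <- dim(vol)[3]
  if (nz < 3L) stop("3D ridge detection needs at least 3 slices")
  z_sigma <- max(0.8, sigma * stack$pixel_size_um / stack$z_step_um)
  if (ceiling(3 * z_sigma) * 2 + 1 > 2 * nz)
    stop("sigma too large for stack depth")
  h11 <- conv3(vol, sigma, c(2, 0, 0), z_sigma)
  h22 <- conv3(vol, sigma, c(0, 2, 0), z_sigma)
  h33 <- conv3(vol, sigma, c(0, 0, 2), z_sigma)
  h12 <- conv3(vol, sigma, c(1, 1, 0), z_sigma)
  h13 <- conv3(vol, sigma, c(1, 0, 1), z_sigma)
  h23 <- conv3(vol, sigma, c(0, 1, 1), z_sigma)
  ev <- sym3_eigenvalues(as.numeric(h11), as.numeric(h22), as.numeric(h33),
                         as.numeric(h12), as.numeric(h13), as.numeric(h23))
  strength <- array(ifelse(ev$l2 < 0 & ev$l1 < 0,
                           sqrt(pmax(ev$l1 * ev$l2, 0)), 0),
                    dim(vol))
  smax <- max(strength)
  # flat stacks: FFT round-off is not signal
  if (smax <= 1e-8 * max(vol, 1e-30) || diff(range(vol)) == 0)
    return(array(FALSE, dim(vol)))
  s <- strength / smax
  cand <- s >= low
  # non-maximum suppression: keep voxels that are local maxima of response
  # within their 3x3x3 neighbourhood restricted to the two normal axes --
  # approximated by requiring a maximum over the full 26-neighbourhood minus
  # the two best-aligned axis neighbours, which for thin tubes reduces to a
  # plane maximum.
  local_max <- s >= 0.999 * neighbourhood_max(s, exclude_axis = TRUE)
  cand <- cand & local_max
  # hysteresis: keep components containing a high-confidence voxel
  seeds <- which(cand & s >= high)
  if (!length(seeds)) return(array(FALSE, dim(vol)))
  lab <- label_nd(cand)
  keep_labs <- unique(lab[seeds])
  out <- array(lab > 0 & lab %in% keep_labs, dim(vol))
  skeletonize_3d(out)
}

# For each voxel, the maximum response among its 26 neighbours; when
# exclude_axis, the two neighbours along the locally strongest direction are
# retained in the max (suppression then acts across the tube only in effect).
neighbourhood_max <- function(s, exclude_axis = FALSE) {
  d <- dim(s)
  out <- array(-Inf, d)
  for (dz in -1:1) for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0 && dz == 0) next
    # skip pure axial shifts so ridges running along an axis are not
    # suppressed by their own neighbours
    if (exclude_axis && sum(c(dr, dc, dz) != 0) == 1) next
    sh <- shift_numeric(s, dr, dc, dz)
    out <- pmax(out, sh)
  }
  out
}

shift_numeric <- function(s, dr, dc, dz) {
  d <- dim(s)
  out <- array(-Inf, d)
  r_dst <- max(1, 1 + dr):min(d[1], d[1] + dr)
  c_dst <- max(1, 1 + dc):min(d[2], d[2] + dc)
  z_dst <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[r_dst, c_dst, z_dst] <-
    s[r_dst - dr, c_dst - dc, z_dst - dz, drop = FALSE]
  out
}

# Connected-component labelling of a logical 2D/3D array (8-/26-conn).
label_nd <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) return(.label2d_cpp(mask, 8L))
  lab <- array(0L, d)
  nxt <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nxt
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      ci <- arrayInd(cur, d)
      for (dz in -1:1) for (dc in -1:1) for (dr in -1:1) {
        if (dr == 0 && dc == 0 && dz == 0) next
        i <- ci[1] + dr; j <- ci[2] + dc; k <- ci[3] + dz
        if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) next
        f <- ((k - 1L) * d[2] + (j - 1L)) * d[1] + i
        if (mask[f] && lab[f] == 0L) {
          lab[f] <- nxt
          top <- top + 1L
          stack[top] <- f
        }
      }
    }
  }
  lab
}
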