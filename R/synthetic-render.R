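# Rendering synthetic scenes to confocal-like stacks.
#
# Fibres are tubes of constant intensity around their centreline polyline and
# ganglia are flat ellipsoids: the support of the pre-blur, pre-noise signal
# IS the ground-truth mask, so the noiseless limit is exactly two-valued and
# every downstream stage can be validated against an analytic truth. Optical
# realism (smooth intensity profiles) comes from the Gaussian PSF, shot noise
# from a Poisson photon model, and read noise from an additive Gaussian term.

# z (slice units) -> pseudo-pixel coordinate so distances are Euclidean in px
z_to_px <- function(z, render) (z - 1) * render$z_step_um / render$pixel_size_um

# Rasterize the exact tube/blob support of a graph into a 3D logical array.
raster_mask <- function(graph, render) {
  nz <- render$shape[1]; nr <- render$shape[2]; nc <- render$shape[3]
  zs <- render$z_step_um / render$pixel_size_um
  r_t <- graph$spec$fibre_width_px / 2
  mask <- array(FALSE, c(nr, nc, nz))
  mark_segment <- function(A, B, radius) {
    # A, B: c(row, col, z_slice); radius in px
    Az <- z_to_px(A[3], render); Bz <- z_to_px(B[3], render)
    rz <- radius / zs + 1e-9
    r0 <- max(1L, floor(min(A[1], B[1]) - radius - 1))
    r1 <- min(nr, ceiling(max(A[1], B[1]) + radius + 1))
    c0 <- max(1L, floor(min(A[2], B[2]) - radius - 1))
    c1 <- min(nc, ceiling(max(A[2], B[2]) + radius + 1))
    z0 <- max(1L, floor(min(A[3], B[3]) - rz - 1))
    z1 <- min(nz, ceiling(max(A[3], B[3]) + rz + 1))
    if (r0 > r1 || c0 > c1 || z0 > z1) return(invisible())
    rs <- r0:r1; cs <- c0:c1; zp <- z_to_px(z0:z1, render)
    nR <- length(rs); nC <- length(cs); nZ <- length(zp)
    R <- array(rs, c(nR, nC, nZ))
    C <- array(rep(cs, each = nR), c(nR, nC, nZ))
    Z <- array(rep(zp, each = nR * nC), c(nR, nC, nZ))
    d <- c(B[1] - A[1], B[2] - A[2], Bz - Az)
    len2 <- sum(d^2)
    if (len2 == 0) {
      d2 <- (R - A[1])^2 + (C - A[2])^2 + (Z - Az)^2
    } else {
      t <- ((R - A[1]) * d[1] + (C - A[2]) * d[2] + (Z - Az) * d[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (R - A[1] - t * d[1])^2 + (C - A[2] - t * d[2])^2 +
            (Z - Az - t * d[3])^2
    }
    hit <- d2 <= radius^2
    mask[r0:r1, c0:c1, z0:z1] <<- mask[r0:r1, c0:c1, z0:z1] | hit
    invisible()
  }
  for (e in graph$edges) {
    p <- e$path
    for (s in seq_len(nrow(p) - 1L)) mark_segment(p[s, ], p[s + 1L, ], r_t)
  }
  gang <- graph$nodes[graph$nodes$kind == "ganglion", , drop = FALSE]
  for (i in seq_len(nrow(gang))) {
    g <- gang[i, ]
    Rg <- g$radius_px
    Rz_px <- max(zs, 0.5 * Rg)
    z0px <- z_to_px(g$z, render)
    r0 <- max(1L, floor(g$row - Rg)); r1 <- min(nr, ceiling(g$row + Rg))
    c0 <- max(1L, floor(g$col - Rg)); c1 <- min(nc, ceiling(g$col + Rg))
    zr <- Rz_px / zs
    z0 <- max(1L, floor(g$z - zr)); z1 <- min(nz, ceiling(g$z + zr))
    rs <- r0:r1; cs <- c0:c1; zp <- z_to_px(z0:z1, render)
    nR <- length(rs); nC <- length(cs); nZ <- length(zp)
    R <- array(rs, c(nR, nC, nZ))
    C <- array(rep(cs, each = nR), c(nR, nC, nZ))
    Z <- array(rep(zp, each = nR * nC), c(nR, nC, nZ))
    hit <- ((R - g$row)^2 + (C - g$col)^2) / Rg^2 +
           (Z - z0px)^2 / Rz_px^2 <= 1
    mask[r0:r1, c0:c1, z0:z1] <- mask[r0:r1, c0:c1, z0:z1] | hit
  }
  mask
}

# PSF blur + photon (Poisson) + read (Gaussian) noise on a clean signal.
apply_optics_and_noise <- function(signal, render, seed) {
  vox <- signal
  nz <- dim(vox)[3]
  if (render$psf_sigma_px[1] > 0)
    vox <- EBImage::imageData(EBImage::gblur(vox,
                                             sigma = render$psf_sigma_px[1]))
  if (render$psf_sigma_px[2] > 0 && nz > 1L)
    vox <- conv_z(vox, gauss_kernel1d(render$psf_sigma_px[2], 0L))
  with_seed(seed, {
    if (is.finite(render$photon_scale))
      vox[] <- stats::rpois(length(vox), pmax(vox, 0) * render$photon_scale) /
        render$photon_scale
    if (render$gauss_noise_sd > 0)
      vox[] <- vox + stats::rnorm(length(vox), 0, render$gauss_noise_sd)
  })
  pmax(vox, 0)
}

#' Render a network graph to a confocal-like stack
#'
#' Draws constant-intensity tubes of the spec's fibre width along every edge
#' and flat ellipsoidal soma clusters at ganglion nodes, applies a Gaussian
#' PSF (lateral and axial), Poisson shot noise scaled by `photon_scale`, and
#' additive Gaussian read noise over a constant background. The ground-truth
#' mask is the exact pre-blur, pre-noise support.
#'
#' @param graph an `ens_graph` from [generate_network_graph()].
#' @param render a [render_params()]; must match the graph's volume.
#' @param seed integer seed for the noise realization.
#' @return List with `stack` (an [image_stack()]) and `truth` (a
#'   [graph_truth()] augmented with `true_mask` (3D logical),
#'   `true_mask_2d`, `true_density_fraction`, `true_orientation_deg`).
#' @export
render_stack <- function(graph, render, seed = 1L) {
  stopifnot(inherits(graph, "ens_graph"), inherits(render, "RenderParams"))
  if (!all(graph$shape == render$shape))
    stop("graph volume does not match render shape")
  mask <- raster_mask(graph, render)
  signal <- render$background_level + 1.0 * mask
  vox <- apply_optics_and_noise(signal, render, seed)
  truth <- graph_truth(graph)
  truth$true_mask <- mask
  m2 <- mask[, , 1]
  if (dim(mask)[3] > 1L)
    for (k in 2:dim(mask)[3]) m2 <- m2 | mask[, , k]
  truth$true_mask_2d <- m2
  truth$true_density_fraction <- mean(m2)
  truth$true_orientation_deg <-
    if (graph$spec$anisotropy > 0) graph$spec$preferred_axis_deg else NA_real_
  list(stack = image_stack(vox, render$pixel_size_um, render$z_step_um,
                           list(source = "synthetic", seed = seed)),
       truth = truth)
}

#' Generate a synthetic soma (HuC/D-like) scene
#'
#' Places `n_somata` non-overlapping flat discs (minimum centre distance 2.5
#' radii) in a single-slice field, optionally adds sub-threshold "debris"
#' blobs smaller than the 10 um^2 counting filter, and renders with the same
#' optics/noise model as network scenes.
#'
#' @param n_somata number of somata (>= 0).
#' @param radius_um mean soma radius in micrometres.
#' @param render a [render_params()]; default is a single 512 x 512 slice.
#' @param seed integer seed.
#' @param n_debris number of sub-10-um^2 debris blobs to add.
#' @param debris_radius_um range of debris radii (um); the default keeps
#'   every debris blob below the 10 um^2 area filter.
#' @return List: `image` (calibrated matrix), `true_soma_count`, `true_mask`
#'   (somata only), `centers`, `radii_px`, `debris_areas_um2`.
#' @export
generate_soma_scene <- function(n_somata, radius_um = 6,
                                render = render_params(shape = c(1L, 512L, 512L)),
                                seed = 1L, n_debris = 0L,
                                debris_radius_um = c(0.6, 1.5)) {
  stopifnot(n_somata >= 0, radius_um > 0)
  nr <- render$shape[2]; nc <- render$shape[3]
  r_px <- radius_um / render$pixel_size_um
  with_seed(substream_seed(seed, 11L), {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n_somata) {
      if (tries > 400L * max(n_somata, 1L))
        stop("cannot place ", n_somata, " non-overlapping somata")
      tries <- tries + 1L
      rr <- runif(1, r_px + 2, nr - r_px - 2)
      cc <- runif(1, r_px + 2, nc - r_px - 2)
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - rr)^2 + (centers[, 2] - cc)^2)) >= 2.5 * r_px) {
        centers <- rbind(centers, c(rr, cc))
        radii <- c(radii, runif(1, 0.9, 1.1) * r_px)
      }
    }
    # debris: small blobs below the counting filter, clear of all somata
    debris <- matrix(numeric(0), 0, 3)
    d_tries <- 0L
    while (nrow(debris) < n_debris) {
      if (d_tries > 400L * max(n_debris, 1L))
        stop("cannot place ", n_debris, " debris blobs")
      d_tries <- d_tries + 1L
      rd <- runif(1, debris_radius_um[1], debris_radius_um[2]) /
        render$pixel_size_um
      rr <- runif(1, rd + 2, nr - rd - 2)
      cc <- runif(1, rd + 2, nc - rd - 2)
      clear <- nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - rr)^2 + (centers[, 2] - cc)^2) - radii) >
          rd + 4
      clear <- clear && (nrow(debris) == 0 ||
        min(sqrt((debris[, 1] - rr)^2 + (debris[, 2] - cc)^2) - debris[, 3]) >
          rd + 4)
      if (clear) debris <- rbind(debris, c(rr, cc, rd))
    }
    disc <- function(mask, rr, cc, rad) {
      r0 <- max(1L, floor(rr - rad)); r1 <- min(nr, ceiling(rr + rad))
      c0 <- max(1L, floor(cc - rad)); c1 <- min(nc, ceiling(cc + rad))
      rs <- r0:r1; cs <- c0:c1
      hit <- outer(rs, cs, function(i, j) (i - rr)^2 + (j - cc)^2 <= rad^2)
      mask[rs, cs] <- mask[rs, cs] | hit
      mask
    }
    soma_mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(centers)))
      soma_mask <- disc(soma_mask, centers[i, 1], centers[i, 2], radii[i])
    full_mask <- soma_mask
    for (i in seq_len(nrow(debris)))
      full_mask <- disc(full_mask, debris[i, 1], debris[i, 2], debris[i, 3])
    signal <- array(render$background_level + 1.0 * full_mask, c(nr, nc, 1L))
    vox <- apply_optics_and_noise(signal, render, substream_seed(seed, 12L))
    img <- vox[, , 1]
    attr(img, "pixel_size_um") <- render$pixel_size_um
    list(image = img, true_soma_count = as.integer(n_somata),
         true_mask = soma_mask, centers = centers, radii_px = radii,
         debris_areas_um2 = if (nrow(debris)) pi * (debris[, 3] *
           render$pixel_size_um)^2 else numeric(0))
  })
}

#' Synthetic stripe pattern at a known orientation
#'
#' Sinusoidal stripes whose long axis lies at `theta_deg` (mathematical
#' convention: 0 deg horizontal, positive counter-clockwise, reported in
#' -90..+90). Used to validate orientation recovery.
#'
#' @param shape `c(rows, cols)`.
#' @param theta_deg stripe orientation in degrees.
#' @param period stripe period in pixels.
#' @param contrast amplitude of the modulation (0-1).
#' @return A numeric matrix in `[0, 1]`.
#' @export
stripe_pattern <- function(shape = c(256L, 256L), theta_deg = 0, period = 12,
                           contrast = 1) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  phase <- 2 * pi * (c_ * sin(th) + r * cos(th)) / period
  0.5 + 0.5 * contrast * sin(phase)
}
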