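# Structure-tensor orientation and coherency of fibre networks.
#
# Orientation is axial (a fibre at theta is the same fibre at theta + 180),
# reported in (-90, +90] degrees with 0 horizontal and positive angles
# counter-clockwise. Coherency is the normalized eigenvalue contrast
# (l1 - l2) / (l1 + l2): 0 isotropic, 1 perfectly oriented.

#' Per-pixel structure tensor
#'
#' Gaussian-windowed outer product of the intensity gradient: components
#' `Jrr`, `Jcc`, `Jrc` (row/col derivatives at `gradient_sigma`, window at
#' `window_sigma`). Symmetric positive semi-definite per pixel.
#'
#' @param image numeric matrix.
#' @param gradient_sigma derivative scale (px).
#' @param window_sigma tensor-averaging window (px).
#' @return List of matrices `Jrr`, `Jcc`, `Jrc`.
#' @export
structure_tensor <- function(image, gradient_sigma = 1, window_sigma = 4) {
  stopifnot(gradient_sigma > 0, window_sigma > 0)
  k0 <- gauss_kernel1d(gradient_sigma, 0L)
  k1 <- gauss_kernel1d(gradient_sigma, 1L)
  gr <- conv_sep(image, k1, k0)  # d/drow
  gc <- conv_sep(image, k0, k1)  # d/dcol
  w <- gauss_kernel1d(window_sigma, 0L)
  list(Jrr = conv_sep(gr * gr, w, w),
       Jcc = conv_sep(gc * gc, w, w),
       Jrc = conv_sep(gr * gc, w, w))
}

#' Orientation and coherency analysis
#'
#' Per-pixel fibre orientation (the structure axis, perpendicular to the
#' dominant gradient) and coherency from the structure tensor, plus
#' image-level summaries: an energy-weighted coherency, the axial circular
#' mean orientation (doubled-angle vector mean, the statistically correct
#' average of axial data), and the naive arithmetic mean of per-pixel
#' orientations. The naive mean is retained because vertically oriented
#' images make it unstable -- pixels register near +90 or -90 essentially at
#' random, so the arithmetic average can land anywhere -- whereas the
#' circular mean stays pinned at +-90.
#'
#' @param image numeric matrix.
#' @param gradient_sigma,window_sigma tensor scales, see
#'   [structure_tensor()].
#' @param mask optional logical matrix restricting the summary statistics.
#' @return An `OrientationResult`: list with `orientation_deg` /
#'   `coherency` maps, scalars `mean_orientation_deg` (axial circular mean),
#'   `raw_arithmetic_mean_deg`, `coherency_mean` (0-1),
#'   `coherency_percent`, and the tensor scales.
#' @export
orientation_and_coherency <- function(image, gradient_sigma = 1,
                                      window_sigma = 4, mask = NULL) {
  J <- structure_tensor(image, gradient_sigma, window_sigma)
  tr <- J$Jrr + J$Jcc
  disc <- sqrt(pmax((J$Jrr - J$Jcc)^2 + 4 * J$Jrc^2, 0))
  coh <- ifelse(tr > 0, pmin(pmax(disc / tr, 0), 1), 0)
  # dominant gradient axis angle (image coords, row axis down):
  phi <- 0.5 * atan2(2 * J$Jrc, J$Jcc - J$Jrr)
  # structure axis is perpendicular; convert to math convention (y up)
  theta <- -(phi * 180 / pi + 90)
  theta <- ((theta + 90) %% 180) - 90
  theta[theta <= -90] <- theta[theta <= -90] + 180
  sel <- if (is.null(mask)) rep(TRUE, length(theta)) else as.vector(mask)
  w <- as.vector(tr)[sel]
  th <- as.vector(theta)[sel]
  ch <- as.vector(coh)[sel]
  if (sum(w) <= 0) w <- rep(1, length(th))
  # axial circular mean: vector mean on doubled angles, weighted by tensor
  # energy x coherency so structureless pixels do not dilute it
  ww <- w * ch
  if (sum(ww) <= 0) ww <- w
  C2 <- sum(ww * cos(2 * th * pi / 180)) / sum(ww)
  S2 <- sum(ww * sin(2 * th * pi / 180)) / sum(ww)
  circ_mean <- atan2(S2, C2) / 2 * 180 / pi
  if (circ_mean <= -90) circ_mean <- circ_mean + 180
  if (circ_mean > 90) circ_mean <- circ_mean - 180
  # image coherency from the summed tensor: random local orientations
  # cancel, so isotropic images score near 0 (a mean of local coherencies
  # would not vanish under the null)
  Srr <- sum(as.vector(J$Jrr)[sel]); Scc <- sum(as.vector(J$Jcc)[sel])
  Src <- sum(as.vector(J$Jrc)[sel])
  coh_mean <- if (Srr + Scc > 0)
    sqrt((Srr - Scc)^2 + 4 * Src^2) / (Srr + Scc) else 0
  structure(list(orientation_deg = theta, coherency = coh,
                 mean_orientation_deg = circ_mean,
                 raw_arithmetic_mean_deg = mean(th),
                 coherency_mean = coh_mean,
                 coherency_percent = 100 * coh_mean,
                 gradient_sigma = gradient_sigma,
                 window_sigma = window_sigma),
            class = "OrientationResult")
}

#' @export
print.OrientationResult <- function(x, ...) {
  cat(sprintf("OrientationResult: axial mean %.1f deg (naive %.1f deg), coherency %.3f\n",
              x$mean_orientation_deg, x$raw_arithmetic_mean_deg,
              x$coherency_mean))
  invisible(x)
}

#' Hue-saturation-brightness orientation map
#'
#' Hue encodes orientation linearly over 180 degrees, saturation encodes
#' coherency, and brightness the (normalized) source intensity.
#'
#' @param image numeric matrix (source intensity).
#' @param result an [orientation_and_coherency()] result with maps matching
#'   `image`.
#' @return rows x cols x 3 RGB array in `[0, 1]`.
#' @export
hsb_orientation_map <- function(image, result) {
  stopifnot(inherits(result, "OrientationResult"),
            all(dim(image) == dim(result$orientation_deg)))
  h <- (result$orientation_deg + 90) / 180
  h[h >= 1] <- 0
  s <- pmin(pmax(result$coherency, 0), 1)
  rng <- range(image)
  v <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  cols <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), c(dim(image), 3L))
}

#' Decode orientation back from an HSB map's hue channel
#'
#' @param rgb rows x cols x 3 array from [hsb_orientation_map()].
#' @return Matrix of orientations in degrees.
#' @export
hsb_decode_orientation <- function(rgb) {
  h <- grDevices::rgb2hsv(rbind(as.vector(rgb[, , 1]) * 255,
                                as.vector(rgb[, , 2]) * 255,
                                as.vector(rgb[, , 3]) * 255))[1, ]
  matrix(h * 180 - 90, dim(rgb)[1], dim(rgb)[2])
}
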