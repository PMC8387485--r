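# Automated soma (HuC/D-like) counting: threshold, connected components,
# size/circularity filter, per-subject averaging.

#' Particle filter settings
#'
#' Defaults reproduce the counting filter used for HuC/D+ neurons:
#' size 10 um^2 to infinity, circularity 0.00-1.00.
#'
#' @param min_area_um2,max_area_um2 area window in um^2.
#' @param circularity_min,circularity_max circularity window; circularity is
#'   `4 pi area / perimeter^2` (Crofton perimeter), clamped to `[0, 1]`.
#' @return A `ParticleFilter` list.
#' @export
particle_filter <- function(min_area_um2 = 10, max_area_um2 = Inf,
                            circularity_min = 0, circularity_max = 1) {
  stopifnot(min_area_um2 <= max_area_um2,
            circularity_min <= circularity_max)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 circularity_min = circularity_min,
                 circularity_max = circularity_max),
            class = "ParticleFilter")
}

# Crofton 4-direction perimeter estimate of one labelled component.
crofton_perimeter <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  transitions <- function(a, b) sum(a != b)
  n_h <- transitions(m[, -1], m[, -ncol(m)])          # along rows
  n_v <- transitions(m[-1, ], m[-nrow(m), ])          # along cols
  n_d1 <- transitions(m[-1, -1], m[-nrow(m), -ncol(m)])
  n_d2 <- transitions(m[-1, -ncol(m)], m[-nrow(m), -1])
  # Cauchy-Crofton with 4 directions: P = (pi/2) * mean intersection count,
  # line spacings 1 (axes) and 1/sqrt(2) (diagonals)
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Count somata in a calibrated image
#'
#' Otsu auto-threshold, 8-connected component labelling, conversion of
#' areas to um^2 via the pixel size, then the particle filter; touching
#' somata are not split (no watershed) unless `watershed = TRUE`.
#'
#' @param image numeric matrix; pixel size read from its `pixel_size_um`
#'   attribute unless given.
#' @param pixel_size_um lateral calibration (um/px).
#' @param filter a [particle_filter()].
#' @param watershed split touching blobs with a distance-map watershed
#'   before filtering.
#' @return List: `count`, and `particles` (data.frame: label, area_px,
#'   area_um2, perimeter_px, circularity, centroid_row, centroid_col).
#' @export
count_somata <- function(image, pixel_size_um = attr(image, "pixel_size_um"),
                         filter = particle_filter(), watershed = FALSE) {
  stopifnot(is.matrix(image), inherits(filter, "ParticleFilter"))
  if (is.null(pixel_size_um)) stop("pixel_size_um must be supplied")
  mask <- auto_threshold(image)
  if (watershed) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(EBImage::watershed(dm))
    storage.mode(lab) <- "integer"
  } else {
    lab <- .label2d_cpp(mask, 8L)
  }
  n <- max(lab)
  if (n == 0L)
    return(list(count = 0L, particles = data.frame(
      label = integer(0), area_px = integer(0), area_um2 = numeric(0),
      perimeter_px = numeric(0), circularity = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0))))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  areas <- tabulate(l, n)
  tab <- data.frame(label = seq_len(n), area_px = areas,
                    area_um2 = areas * pixel_size_um^2,
                    perimeter_px = NA_real_, circularity = NA_real_,
                    centroid_row = as.numeric(tapply(rows, l, mean)),
                    centroid_col = as.numeric(tapply(cols, l, mean)))
  for (i in seq_len(n)) {
    sel <- l == i
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    sub <- matrix(FALSE, diff(r0) + 1L, diff(c0) + 1L)
    sub[cbind(rows[sel] - r0[1] + 1L, cols[sel] - c0[1] + 1L)] <- TRUE
    p <- crofton_perimeter(sub)
    tab$perimeter_px[i] <- p
    tab$circularity[i] <- if (p > 0)
      min(1, max(0, 4 * pi * areas[i] / p^2)) else 1
  }
  keep <- tab$area_um2 >= filter$min_area_um2 &
    tab$area_um2 <= filter$max_area_um2 &
    tab$circularity >= filter$circularity_min &
    tab$circularity <= filter$circularity_max
  list(count = sum(keep), particles = tab[keep, , drop = FALSE])
}

#' Per-subject averaging of field counts
#'
#' The subject (animal) is the statistical unit: each subject's fields are
#' averaged first, then the group is summarized over subject means.
#'
#' @param counts data.frame with columns `subject`, `count` and optionally
#'   `group`.
#' @return List: `per_subject` (subject means) and `group_summary`
#'   (mean, sd, sem, n over subject means, per group).
#' @export
average_counts <- function(counts) {
  stopifnot(all(c("subject", "count") %in% names(counts)))
  if (!nrow(counts)) stop("empty counts table")
  if (is.null(counts$group)) counts$group <- "all"
  per_subject <- aggregate(count ~ group + subject, counts, mean)
  names(per_subject)[3] <- "mean_count"
  gs <- do.call(rbind, lapply(split(per_subject, per_subject$group),
    function(g) data.frame(group = g$group[1], n = nrow(g),
                           mean = mean(g$mean_count),
                           sd = stats::sd(g$mean_count),
                           sem = stats::sd(g$mean_count) / sqrt(nrow(g)))))
  rownames(gs) <- NULL
  list(per_subject = per_subject, group_summary = gs)
}
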