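# Network density and the binned interganglionic ("negative-space") census.

#' Network density of a binary mask
#'
#' 100 x foreground pixels / total pixels: the fraction of a z-projected
#' field covered by the segmented neural network.
#'
#' @param mask logical matrix.
#' @return Density in percent.
#' @export
network_density <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (length(mask) == 0L) stop("empty mask")
  100 * sum(mask) / length(mask)
}

#' Interganglionic (background-component) areas
#'
#' Connected components of the mask's logical complement, used as a proxy for
#' the spaces between ganglia. Background uses 4-connectivity by default (the
#' standard dual of 8-connected foreground); components touching the border
#' are included unless `exclude_border`.
#'
#' @param mask logical matrix (TRUE = network).
#' @param connectivity 4 or 8.
#' @param exclude_border drop components touching the image border.
#' @return Integer vector of component areas (pixel counts), ordered by
#'   component centroid (row-major).
#' @export
interganglionic_areas <- function(mask, connectivity = 4L,
                                  exclude_border = FALSE) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- .label2d_cpp(!mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(integer(0))
  areas <- tabulate(lab, n)
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  cr <- tapply(rows, l, mean)
  cc <- tapply(cols, l, mean)
  keep <- seq_len(n)
  if (exclude_border) {
    border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border_labs[border_labs > 0])
    if (!length(keep)) return(integer(0))
  }
  ord <- order(cr[as.character(keep)], cc[as.character(keep)])
  as.integer(areas[keep][ord])
}

#' Fill small background holes in a mask
#'
#' Sets background components (4-connectivity) of at most `max_px` pixels
#' that do not touch the image border to foreground. Used before
#' skeletonization so sub-fibre pinholes do not spawn spurious loops; the
#' interganglionic-area census always runs on the unfilled mask.
#'
#' @param mask logical matrix.
#' @param max_px largest hole area to fill (px).
#' @return The filled mask.
#' @export
fill_holes <- function(mask, max_px = 9) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (max_px <= 0) return(mask)
  lab <- .label2d_cpp(!mask, 4L)
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab, n)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  fill <- setdiff(which(areas <= max_px), border)
  mask[lab %in% fill] <- TRUE
  mask
}

#' Interganglionic-area bin scheme
#'
#' The seven-size census used for negative-space areas: very small (0-50 px),
#' small (51-200, 201-400), medium (401-600, 601-800) and large (801-1000
#' and greater than 1000). Edges are integer-inclusive.
#'
#' @param edges upper edges of the first six bins (strictly increasing).
#' @return An `AreaBinScheme`: list with `edges` and `labels`.
#' @export
area_bin_scheme <- function(edges = c(50L, 200L, 400L, 600L, 800L, 1000L)) {
  stopifnot(all(diff(edges) > 0), all(edges > 0))
  labels <- c(sprintf("0-%d", edges[1]),
              sprintf("%d-%d", edges[-length(edges)] + 1L, edges[-1]),
              sprintf(">%d", edges[length(edges)]))
  structure(list(edges = as.integer(edges), labels = labels),
            class = "AreaBinScheme")
}

#' Bin areas into the size census
#'
#' @param areas non-negative integer areas (px^2).
#' @param scheme an [area_bin_scheme()].
#' @return Named integer vector of counts, one per bin; sums to
#'   `length(areas)`.
#' @export
bin_areas <- function(areas, scheme = area_bin_scheme()) {
  stopifnot(inherits(scheme, "AreaBinScheme"))
  if (length(areas) && (any(areas < 0) || any(areas != floor(areas))))
    stop("areas must be non-negative integers")
  nb <- length(scheme$edges) + 1L
  if (!length(areas)) {
    out <- integer(nb); names(out) <- scheme$labels; return(out)
  }
  bin <- findInterval(areas, scheme$edges + 0.5) + 1L
  out <- tabulate(bin, nb)
  names(out) <- scheme$labels
  out
}
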