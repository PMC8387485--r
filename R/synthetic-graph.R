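# Geometric ENS network generation with exact ground truth.
#
# A scene is a graph embedded in the render volume: ganglion nodes on a
# jittered lattice, connective fibre polylines between lattice neighbours,
# and secondary fibres ("sprouts") branching off connectives. Sprout
# placement is rejection-sampled so that no two unrelated fibres come within
# a fibre width of each other: the rendered topology then equals the graph
# topology, which is what makes exact ground truth possible.

seg_len <- function(p) {
  if (nrow(p) < 2L) return(0)
  d <- diff(p[, 1:2, drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

seg_len3 <- function(p, z_scale = 1) {
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  d[, 3] <- d[, 3] * z_scale
  sum(sqrt(rowSums(d^2)))
}

# Min 2D distance from points (m x 2: row, col) to a polyline (n x >=2).
points_polyline_dist <- function(pts, poly) {
  n <- nrow(poly) - 1L
  S <- cbind(poly[seq_len(n), 1], poly[seq_len(n), 2],
             poly[seq_len(n) + 1L, 1], poly[seq_len(n) + 1L, 2])
  points_segments_dist(pts, S)
}

# Precompute segment geometry (a, direction, squared length) for repeated
# point-to-segment-set distance queries.
prep_segments <- function(S) {
  dr <- S[, 3] - S[, 1]; dc <- S[, 4] - S[, 2]
  list(a1 = S[, 1], a2 = S[, 2], dr = dr, dc = dc,
       len2 = pmax(dr^2 + dc^2, 1e-12), n = nrow(S))
}

# Squared distances (s x m) from points (m x 2) to prepared segments.
segments_points_dist2_prep <- function(pts, P) {
  s <- P$n; m <- nrow(pts)
  PR <- matrix(pts[, 1], s, m, byrow = TRUE) - P$a1  # s x m
  PC <- matrix(pts[, 2], s, m, byrow = TRUE) - P$a2
  t <- (PR * P$dr + PC * P$dc) / P$len2
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- PR - t * P$dr
  dy <- PC - t * P$dc
  dx * dx + dy * dy
}

segments_points_dist2 <- function(pts, S) {
  segments_points_dist2_prep(pts, prep_segments(S))
}

# Minimum distance from a point set to a segment set (scalar).
min_segments_dist <- function(pts, S) {
  if (!nrow(S)) return(Inf)
  sqrt(min(segments_points_dist2(pts, S)))
}

min_segments_dist_prep <- function(pts, P) {
  if (P$n == 0L) return(Inf)
  sqrt(min(segments_points_dist2_prep(pts, P)))
}

points_segments_dist <- function(pts, S) {
  sqrt(apply(segments_points_dist2(pts, S), 2L, min))
}

# Evaluate a point at arc-length fraction t along a polyline; returns
# c(row, col, z, drow, dcol) with (drow, dcol) the local unit direction.
polyline_point <- function(poly, t) {
  d <- diff(poly[, 1:2, drop = FALSE])
  sl <- sqrt(rowSums(d^2))
  cs <- c(0, cumsum(sl))
  target <- t * cs[length(cs)]
  s <- max(1L, findInterval(target, cs, rightmost.closed = TRUE))
  s <- min(s, nrow(poly) - 1L)
  f <- if (sl[s] > 0) (target - cs[s]) / sl[s] else 0
  p <- poly[s, ] + f * (poly[s + 1L, ] - poly[s, ])
  dir <- (poly[s + 1L, 1:2] - poly[s, 1:2]) / max(sl[s], 1e-9)
  c(p, dir)
}

#' Generate a synthetic ENS network graph
#'
#' Builds a ganglion-lattice network embedded in the render volume: ganglia
#' at jittered lattice sites, fibre connectives between lattice neighbours
#' (sampled with `connective_prob`, then minimally augmented so the lattice
#' graph is connected), and Poisson-distributed secondary fibres sprouting
#' from connectives. All randomness derives from `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed fixing all randomness.
#' @param shape render volume `(n_slices, height, width)`.
#' @return An `ens_graph`: list with `nodes` (data.frame: id, row, col, z,
#'   kind, radius_px), `edges` (list of `list(from, to, path)` with `path` an
#'   n x 3 polyline in row/col/slice units), `spec`, and `shape`.
#' @export
generate_network_graph <- function(spec, seed, shape = c(21L, 512L, 512L)) {
  stopifnot(inherits(spec, "NetworkSpec"))
  nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
  sp_r <- nr / spec$grid_rows; sp_c <- nc / spec$grid_cols
  w <- spec$fibre_width_px
  margin <- spec$ganglion_radius_px + 2
  if (min(sp_r, sp_c) < 2.5 * spec$ganglion_radius_px ||
      min(sp_r, sp_c) < 4 * w)
    stop("lattice too large for render volume")
  with_seed(seed, {
    gr <- spec$grid_rows; gc <- spec$grid_cols
    idx <- function(i, j) (j - 1L) * gr + i
    n_g <- gr * gc
    rows <- cols <- zs <- numeric(n_g)
    for (j in seq_len(gc)) for (i in seq_len(gr)) {
      k <- idx(i, j)
      rows[k] <- min(max((i - 0.5) * sp_r + rnorm(1, 0, spec$jitter_px), margin), nr - margin)
      cols[k] <- min(max((j - 0.5) * sp_c + rnorm(1, 0, spec$jitter_px), margin), nc - margin)
      zs[k] <- if (nz == 1L) 1 else
        min(max((nz + 1) / 2 + rnorm(1, 0, min(1, nz / 10)), 1.5), nz - 0.5)
    }
    # candidate rook-neighbour pairs
    cand <- NULL
    for (j in seq_len(gc)) for (i in seq_len(gr)) {
      if (i < gr) cand <- rbind(cand, c(idx(i, j), idx(i + 1L, j)))
      if (j < gc) cand <- rbind(cand, c(idx(i, j), idx(i, j + 1L)))
    }
    axis_rad <- spec$preferred_axis_deg * pi / 180
    p_edge <- apply(cand, 1L, function(e) {
      drow <- rows[e[2]] - rows[e[1]]; dcol <- cols[e[2]] - cols[e[1]]
      theta <- atan2(-drow, dcol)  # math convention, y up
      spec$connective_prob * (1 - spec$anisotropy * sin(theta - axis_rad)^2)
    })
    keep <- runif(nrow(cand)) < p_edge
    # connect-by-construction: union-find, add random missing rook edges
    parent <- seq_len(n_g)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    union <- function(a, b) parent[find(a)] <<- find(b)
    for (k in which(keep)) union(cand[k, 1], cand[k, 2])
    off <- which(!keep)
    for (k in sample(off)) {
      if (find(cand[k, 1]) != find(cand[k, 2])) {
        keep[k] <- TRUE
        union(cand[k, 1], cand[k, 2])
      }
    }
    conn <- cand[keep, , drop = FALSE]
    # connective polylines with a small midpoint bend
    polys <- vector("list", nrow(conn))
    for (k in seq_len(nrow(conn))) {
      a <- conn[k, 1]; b <- conn[k, 2]
      A <- c(rows[a], cols[a], zs[a]); B <- c(rows[b], cols[b], zs[b])
      dirv <- (B[1:2] - A[1:2]); len <- sqrt(sum(dirv^2))
      nrm <- c(-dirv[2], dirv[1]) / max(len, 1e-9)
      M <- (A + B) / 2
      M[1:2] <- M[1:2] + nrm * rnorm(1, 0, 0.04 * len)
      if (nz > 1L) M[3] <- min(max(M[3] + rnorm(1, 0, 0.3), 1.2), nz - 0.2)
      polys[[k]] <- rbind(A, M, B)
    }
    # secondary fibres ("sprouts") off connectives, rejection-sampled for
    # clearance so the rendered topology stays equal to the graph topology
    clearance <- w + 2
    gang <- cbind(rows, cols)
    # flatten connective polylines to one segment table for fast clearance
    seg_all <- do.call(rbind, lapply(seq_along(polys), function(m) {
      p <- polys[[m]]; n <- nrow(p) - 1L
      cbind(p[seq_len(n), 1], p[seq_len(n), 2],
            p[seq_len(n) + 1L, 1], p[seq_len(n) + 1L, 2], m)
    }))
    spr_segs <- matrix(numeric(0), 0, 4)
    sprouts <- list()  # each: list(parent, t, base = c(r,c,z), tip = c(r,c,z))
    for (k in seq_len(nrow(conn))) {
      n_spr <- rpois(1, spec$extra_branch_rate)
      if (n_spr == 0) next
      other <- prep_segments(seg_all[seg_all[, 5] != k, 1:4, drop = FALSE])
      own <- prep_segments(seg_all[seg_all[, 5] == k, 1:4, drop = FALSE])
      plen <- seg_len(polys[[k]])
      for (s in seq_len(n_spr)) {
        # draw a batch of candidates, accept the first with full clearance;
        # all candidates are evaluated in one set of vectorized tests
        n_try <- 12L
        tcand <- runif(n_try, 0.25, 0.75)
        signs <- sample(c(-1, 1), n_try, replace = TRUE)
        phis <- runif(n_try, -35, 35) * pi / 180
        # lower bound keeps the free end (beyond the parent tube's radius)
        # comfortably longer than thinning-spur artefacts
        Ls <- runif(n_try, 0.32, 0.45) * min(sp_r, sp_c)
        dzs <- rnorm(n_try, 0, 0.5)
        bases <- t(vapply(tcand, function(t) polyline_point(polys[[k]], t),
                          numeric(5)))
        nrm <- cbind(-bases[, 5], bases[, 4]) * signs
        rot <- cbind(cos(phis) * nrm[, 1] - sin(phis) * nrm[, 2],
                     sin(phis) * nrm[, 1] + cos(phis) * nrm[, 2])
        tips <- bases[, 1:2] + Ls * rot
        ok <- tips[, 1] >= clearance & tips[, 2] >= clearance &
          tips[, 1] <= nr - clearance & tips[, 2] <= nc - clearance
        # sibling bases must be separated along the parent
        for (sp2 in sprouts)
          if (sp2$parent == k)
            ok <- ok & abs(sp2$t - tcand) * plen >= 3 * w
        # clearance samples along each candidate, excluding the base zone
        nsamp <- 6L
        frac <- seq(0, 1, length.out = nsamp)
        # arc positions from just past the base zone to the tip
        s0 <- pmin(pmax(2, w) / Ls, 0.9)
        arc <- outer(frac, 1 - s0, "*") + rep(s0, each = nsamp)  # nsamp x n_try
        arcL <- arc * rep(Ls, each = nsamp)
        pts <- cbind(rep(bases[, 1], each = nsamp) + as.vector(arcL) * rep(rot[, 1], each = nsamp),
                     rep(bases[, 2], each = nsamp) + as.vector(arcL) * rep(rot[, 2], each = nsamp))
        cand_of <- rep(seq_len(n_try), each = nsamp)
        per_cand_min <- function(d2pt) {
          m <- matrix(d2pt, nsamp, n_try)
          apply(m, 2L, min)
        }
        # ganglia: base outside, path clear
        ng <- nrow(gang)
        dg2 <- (matrix(bases[, 1], ng, n_try, byrow = TRUE) - gang[, 1])^2 +
               (matrix(bases[, 2], ng, n_try, byrow = TRUE) - gang[, 2])^2
        ok <- ok & apply(dg2, 2L, min) >= (spec$ganglion_radius_px + 2 * w)^2
        gp2 <- (matrix(pts[, 1], ng, nrow(pts), byrow = TRUE) - gang[, 1])^2 +
               (matrix(pts[, 2], ng, nrow(pts), byrow = TRUE) - gang[, 2])^2
        ok <- ok & per_cand_min(apply(gp2, 2L, min)) >=
          (spec$ganglion_radius_px + w / 2 + 2)^2
        if (any(ok)) {
          # other fibres
          if (other$n)
            ok <- ok & sqrt(per_cand_min(
              apply(segments_points_dist2_prep(pts, other), 2L, min))) >= clearance
          # own parent beyond the immediate base zone, or the two tubes
          # can enclose a background sliver
          d_own <- apply(segments_points_dist2_prep(pts, own), 2L, min)
          d_own[as.vector(arcL) <= 2.5 * w] <- Inf
          ok <- ok & sqrt(per_cand_min(d_own)) >= clearance
          if (nrow(spr_segs))
            ok <- ok & sqrt(per_cand_min(
              apply(segments_points_dist2(pts, spr_segs), 2L, min))) >= clearance
        }
        win <- which(ok)
        if (length(win)) {
          try <- win[1]
          base <- bases[try, 1:3]
          tipz <- if (nz == 1L) 1 else
            min(max(base[3] + dzs[try], 1.2), nz - 0.2)
          sprouts[[length(sprouts) + 1L]] <-
            list(parent = k, t = tcand[try], base = base,
                 tip = c(tips[try, ], tipz))
          spr_segs <- rbind(spr_segs,
                            c(base[1], base[2], tips[try, 1], tips[try, 2]))
        }
      }
    }
    # assemble node table and final edge list (connectives split at sprouts)
    xrow <- c(rows); xcol <- c(cols); xz <- c(zs)
    xkind <- rep("ganglion", n_g)
    xrad <- rep(spec$ganglion_radius_px, n_g)
    edges <- list()
    next_id <- n_g
    for (k in seq_len(nrow(conn))) {
      spr <- Filter(function(s) s$parent == k, sprouts)
      if (length(spr) == 0L) {
        edges[[length(edges) + 1L]] <-
          list(from = conn[k, 1], to = conn[k, 2], path = polys[[k]])
        next
      }
      ord <- order(vapply(spr, function(s) s$t, numeric(1)))
      spr <- spr[ord]
      prev_node <- conn[k, 1]; prev_t <- 0
      for (s in spr) {
        next_id <- next_id + 1L
        xrow <- c(xrow, s$base[1]); xcol <- c(xcol, s$base[2])
        xz <- c(xz, s$base[3]); xkind <- c(xkind, "sprout_base")
        xrad <- c(xrad, 0)
        edges[[length(edges) + 1L]] <-
          list(from = prev_node, to = next_id,
               path = sub_polyline(polys[[k]], prev_t, s$t))
        # the sprout fibre itself, ending at a free tip
        next_id <- next_id + 1L
        xrow <- c(xrow, s$tip[1]); xcol <- c(xcol, s$tip[2])
        xz <- c(xz, s$tip[3]); xkind <- c(xkind, "tip")
        xrad <- c(xrad, 0)
        edges[[length(edges) + 1L]] <-
          list(from = next_id - 1L, to = next_id,
               path = rbind(s$base, s$tip))
        prev_node <- next_id - 1L; prev_t <- s$t
      }
      edges[[length(edges) + 1L]] <-
        list(from = prev_node, to = conn[k, 2],
             path = sub_polyline(polys[[k]], prev_t, 1))
    }
    nodes <- data.frame(id = seq_len(next_id), row = xrow, col = xcol,
                        z = xz, kind = xkind, radius_px = xrad)
    structure(list(nodes = nodes, edges = edges, spec = spec,
                   shape = as.integer(shape)),
              class = "ens_graph")
  })
}

# Extract the sub-polyline between arc-length fractions t0 < t1.
sub_polyline <- function(poly, t0, t1) {
  d <- diff(poly[, 1:2, drop = FALSE])
  sl <- sqrt(rowSums(d^2))
  cs <- c(0, cumsum(sl)); total <- cs[length(cs)]
  a <- polyline_point(poly, t0)[1:3]
  b <- polyline_point(poly, t1)[1:3]
  inner <- which(cs > t0 * total & cs < t1 * total)
  rbind(a, poly[inner, , drop = FALSE], b)
}

#' @export
print.ens_graph <- function(x, ...) {
  cat(sprintf("ens_graph: %d nodes, %d edges in %s volume\n",
              nrow(x$nodes), length(x$edges),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

node_degrees <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  names(deg) <- graph$nodes$id
  for (e in graph$edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1L
    deg[as.character(e$to)] <- deg[as.character(e$to)] + 1L
  }
  deg
}

#' Ground truth of a synthetic network graph
#'
#' Censuses the generated graph the way a skeleton analysis sees it: nodes of
#' degree >= 3 are junctions (triple, quadruple, higher), and branches are
#' the maximal chains of the graph after pass-through (degree-2) nodes are
#' contracted -- a skeleton cannot represent a pass-through ganglion as a
#' node. Raw geometric edge counts are retained alongside.
#'
#' @param graph an `ens_graph`.
#' @return A `GroundTruth` list: `n_triple`, `n_quadruple`, `n_higher`,
#'   `n_junctions`, `n_branches`, `n_endpoints`, `total_branch_length_px`,
#'   `branch_lengths_px` (projected), `n_edges_raw`, `degrees`.
#' @export
graph_truth <- function(graph) {
  deg <- node_degrees(graph)
  n_tri <- sum(deg == 3L); n_quad <- sum(deg == 4L); n_hi <- sum(deg >= 5L)
  # chain contraction: walk from every non-degree-2 node end
  ne <- length(graph$edges)
  lens <- vapply(graph$edges, function(e) seg_len(e$path), numeric(1))
  if (ne == 0L) {
    return(structure(list(
      n_triple = 0L, n_quadruple = 0L, n_higher = 0L, n_junctions = 0L,
      n_branches = 0L, n_endpoints = sum(deg == 1L),
      total_branch_length_px = 0, branch_lengths_px = numeric(0),
      n_edges_raw = 0L, degrees = deg), class = "GroundTruth"))
  }
  inc <- vector("list", nrow(graph$nodes))
  names(inc) <- graph$nodes$id
  for (k in seq_len(ne)) {
    e <- graph$edges[[k]]
    inc[[as.character(e$from)]] <- c(inc[[as.character(e$from)]], k)
    inc[[as.character(e$to)]] <- c(inc[[as.character(e$to)]], k)
  }
  other_end <- function(k, v) {
    e <- graph$edges[[k]]
    if (e$from == v) e$to else e$from
  }
  visited <- logical(ne)
  branch_lengths <- numeric(0)
  terminals <- graph$nodes$id[deg[as.character(graph$nodes$id)] != 2L]
  for (v in terminals) {
    for (k in inc[[as.character(v)]]) {
      if (visited[k]) next
      total <- 0; cur_e <- k; cur_v <- v
      repeat {
        visited[cur_e] <- TRUE
        total <- total + lens[cur_e]
        nxt <- other_end(cur_e, cur_v)
        if (deg[as.character(nxt)] != 2L) break
        es <- inc[[as.character(nxt)]]
        nxt_e <- es[es != cur_e][1]
        if (visited[nxt_e]) break  # pure cycle closed onto itself
        cur_e <- nxt_e; cur_v <- nxt
      }
      branch_lengths <- c(branch_lengths, total)
    }
  }
  # remaining edges are cycles made entirely of degree-2 nodes
  while (any(!visited)) {
    k <- which(!visited)[1]
    total <- 0; cur_e <- k; cur_v <- graph$edges[[k]]$from
    repeat {
      visited[cur_e] <- TRUE
      total <- total + lens[cur_e]
      nxt <- other_end(cur_e, cur_v)
      es <- inc[[as.character(nxt)]]
      nxt_e <- es[es != cur_e][1]
      if (is.na(nxt_e) || visited[nxt_e]) break
      cur_e <- nxt_e; cur_v <- nxt
    }
    branch_lengths <- c(branch_lengths, total)
  }
  structure(list(
    n_triple = n_tri, n_quadruple = n_quad, n_higher = n_hi,
    n_junctions = n_tri + n_quad + n_hi,
    n_branches = length(branch_lengths),
    n_endpoints = sum(deg == 1L),
    total_branch_length_px = sum(branch_lengths),
    branch_lengths_px = branch_lengths,
    n_edges_raw = ne, degrees = deg), class = "GroundTruth")
}

# Keep a subset of edges; node positions unchanged.
subset_edges <- function(graph, keep) {
  g <- graph
  g$edges <- graph$edges[keep]
  g
}

#' Graded network ablation series
#'
#' Emulates graded ENS loss (as in endothelin-receptor-B-null colon): scene
#' `k` keeps each fibre edge with probability `retain_fractions[k]`. A single
#' uniform draw per edge is shared across scenes (common random numbers), so
#' the scene series is nested and ground-truth density and junction counts
#' are monotone non-increasing in expectation and almost surely.
#'
#' @param base a [network_spec()] for the intact network.
#' @param retain_fractions monotone non-increasing vector of retain
#'   probabilities in `[0, 1]`.
#' @param render optional [render_params()]; when supplied each scene is
#'   rendered to an image stack.
#' @param seed integer seed.
#' @return List of scenes: `list(retain, graph, truth, stack, true_mask)`
#'   (`stack`/`true_mask` NULL when `render` is NULL).
#' @export
generate_graded_ablation <- function(base, retain_fractions, render = NULL,
                                     seed = 1L) {
  stopifnot(all(retain_fractions >= 0), all(retain_fractions <= 1))
  if (is.unsorted(rev(retain_fractions)))
    stop("retain_fractions must be monotone non-increasing")
  shape <- if (is.null(render)) c(21L, 512L, 512L) else render$shape
  graph <- generate_network_graph(base, substream_seed(seed, 1L), shape)
  u <- with_seed(substream_seed(seed, 2L), runif(length(graph$edges)))
  lapply(seq_along(retain_fractions), function(k) {
    g <- subset_edges(graph, u <= retain_fractions[k])
    scene <- list(retain = retain_fractions[k], graph = g,
                  truth = graph_truth(g), stack = NULL, true_mask = NULL)
    if (!is.null(render)) {
      r <- render_stack(g, render, substream_seed(seed, 3L, k))
      scene$stack <- r$stack
      scene$true_mask <- r$truth$true_mask
      scene$truth <- r$truth
    }
    scene
  })
}
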