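# Skeleton graph: classify skeleton pixels by neighbour count, merge touching
# junction pixels into junction nodes, trace branches slab-to-slab, and
# census junctions/branches. Works on 2D (8-connectivity) and 3D
# (26-connectivity) skeletons.

neighbour_offsets <- function(nd) {
  if (nd == 2L) {
    g <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  } else {
    g <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
  }
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

#' Build the graph of a thinned skeleton
#'
#' Pixels with one skeleton neighbour are endpoints, with two are branch
#' ("slab") pixels, with three or more are junction candidates; touching
#' junction candidates merge into a single junction node whose degree is the
#' number of distinct emanating branches. Branches are traced slab-to-slab
#' between nodes; length is the calibrated step metric (1, sqrt 2, sqrt 3
#' for axis/diagonal/3D-diagonal steps). Closed loops with no junction
#' become a single self-loop branch. Two cleanups follow: sub-`prune_px`
#' duplicate/self-loop branches from thinning artefacts are pruned, and
#' junction nodes closer (along the skeleton) than `fuse_px` are fused into
#' one node, reflecting that a ganglion-scale crossing is one anatomical
#' junction even when thinning splits it into nearby triple points.
#'
#' @param skeleton logical matrix or 3D logical array (thinned).
#' @param prune_px prune artefactual branches shorter than this (px).
#' @param spur_px prune terminal branches (one free end) shorter than this
#'   (px); 0 disables. Thinning a wide fibre end or a ganglion disc can
#'   leave sub-fibre-width terminal spurs.
#' @param fuse_px fuse junction nodes connected by a branch shorter than
#'   this (px); 0 disables (the raw touching-pixel rule).
#' @param check_thinned verify 2D input is thinning-idempotent and error
#'   otherwise.
#' @return A `SkeletonGraph`: list with `nodes` (data.frame: id, type,
#'   degree, row, col, z, n_pixels), `edges` (data.frame: id, from, to,
#'   length_px, n_slab), `node_pixels`, `edge_paths` (flat pixel indices),
#'   `dim`, `n_skeleton_pixels`.
#' @export
build_graph <- function(skeleton, prune_px = 2, spur_px = 0, fuse_px = 0,
                        check_thinned = FALSE) {
  stopifnot(is.logical(skeleton))
  d <- dim(skeleton)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  if (check_thinned && nd == 2L &&
      !identical(.thin2d_cpp(skeleton), skeleton))
    stop("input is not a thinned skeleton")
  pix <- which(skeleton)
  np <- length(pix)
  empty_nodes <- data.frame(id = integer(0), type = character(0),
                            degree = integer(0), row = numeric(0),
                            col = numeric(0), z = numeric(0),
                            n_pixels = integer(0))
  empty_edges <- data.frame(id = integer(0), from = integer(0),
                            to = integer(0), length_px = numeric(0),
                            n_slab = integer(0))
  if (np == 0L)
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          node_pixels = list(), edge_paths = list(),
                          dim = d, n_skeleton_pixels = 0L),
                     class = "SkeletonGraph"))
  pos <- arrayInd(pix, d)
  idmap <- integer(prod(d))
  idmap[pix] <- seq_len(np)
  offs <- neighbour_offsets(nd)
  adj <- matrix(0L, np, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(pos, 2L, offs[k, ], `+`)
    ok <- rep(TRUE, np)
    for (ax in seq_len(nd))
      ok <- ok & shifted[, ax] >= 1L & shifted[, ax] <= d[ax]
    flat <- rep(0L, np)
    if (nd == 2L)
      flat[ok] <- (shifted[ok, 2] - 1L) * d[1] + shifted[ok, 1]
    else
      flat[ok] <- ((shifted[ok, 3] - 1L) * d[2] + (shifted[ok, 2] - 1L)) * d[1] +
        shifted[ok, 1]
    adj[ok, k] <- idmap[flat[ok]]
  }
  deg_pix <- rowSums(adj > 0L)
  is_junc_pix <- deg_pix >= 3L
  is_end_pix <- deg_pix <= 1L          # includes isolated pixels
  is_node_pix <- is_junc_pix | is_end_pix

  # junction clusters: connected components of junction-candidate pixels
  node_of <- integer(np)
  n_nodes <- 0L
  node_type <- character(0)
  node_members <- list()
  jidx <- which(is_junc_pix)
  if (length(jidx)) {
    seen <- logical(np)
    for (j in jidx) {
      if (seen[j]) next
      n_nodes <- n_nodes + 1L
      comp <- integer(0)
      queue <- j; seen[j] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        comp <- c(comp, cur)
        nb <- adj[cur, ]; nb <- nb[nb > 0L]
        nb <- nb[is_junc_pix[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      node_of[comp] <- n_nodes
      node_type[n_nodes] <- "junction"
      node_members[[n_nodes]] <- comp
    }
  }
  for (e in which(is_end_pix)) {
    n_nodes <- n_nodes + 1L
    node_of[e] <- n_nodes
    node_type[n_nodes] <- if (deg_pix[e] == 0L) "isolated" else "endpoint"
    node_members[[n_nodes]] <- e
  }

  step_len <- function(a, b) sqrt(sum((pos[a, ] - pos[b, ])^2))
  path_len <- function(path) {
    if (length(path) < 2L) return(0)
    sum(vapply(seq_len(length(path) - 1L),
               function(i) step_len(path[i], path[i + 1L]), numeric(1)))
  }

  visited <- logical(np)      # slab pixels consumed by a branch
  e_from <- e_to <- integer(0)
  e_len <- numeric(0)
  e_paths <- list()
  direct_keys <- character(0)

  add_edge <- function(from, to, path) {
    e_from <<- c(e_from, from); e_to <<- c(e_to, to)
    e_len <<- c(e_len, path_len(path))
    e_paths[[length(e_paths) + 1L]] <<- path
  }

  node_pix_order <- which(is_node_pix)
  for (p in node_pix_order) {
    nb <- adj[p, ]; nb <- nb[nb > 0L]
    for (q in nb) {
      if (is_node_pix[q]) {
        if (node_of[q] == node_of[p] && is_junc_pix[p]) next  # intra-cluster
        key <- paste(min(p, q), max(p, q))
        if (key %in% direct_keys) next
        direct_keys <- c(direct_keys, key)
        if (node_of[q] == node_of[p]) next  # same endpoint node: impossible
        add_edge(node_of[p], node_of[q], c(p, q))
      } else if (!visited[q]) {
        # trace a branch through slab pixels
        visited[q] <- TRUE
        path <- c(p, q)
        prev <- p; cur <- q
        repeat {
          nbc <- adj[cur, ]; nbc <- nbc[nbc > 0L]
          nxt <- nbc[!is_node_pix[nbc] & !visited[nbc]]
          if (length(nxt)) {
            nxt <- nxt[1]
            visited[nxt] <- TRUE
            path <- c(path, nxt)
            prev <- cur; cur <- nxt
            next
          }
          ends <- nbc[is_node_pix[nbc] & nbc != prev]
          if (length(ends)) {
            # prefer a different cluster; deterministic first otherwise
            add_edge(node_of[p], node_of[ends[1]], c(path, ends[1]))
          } else if (any(nbc == prev) && is_node_pix[prev]) {
            add_edge(node_of[p], node_of[prev], c(path, prev))  # tiny loop
          } else {
            # dangling end inside slab run (non-thinned artefact): promote
            n_nodes <- n_nodes + 1L
            node_of[cur] <- n_nodes
            node_type[n_nodes] <- "endpoint"
            node_members[[n_nodes]] <- cur
            is_node_pix[cur] <- TRUE
            add_edge(node_of[p], n_nodes, path)
          }
          break
        }
      }
    }
  }
  # pure cycles: remaining unvisited slabs
  remaining <- which(!is_node_pix & !visited & deg_pix > 0L)
  while (length(remaining)) {
    s0 <- remaining[1]
    n_nodes <- n_nodes + 1L
    node_of[s0] <- n_nodes
    node_type[n_nodes] <- "loop"
    node_members[[n_nodes]] <- s0
    visited[s0] <- TRUE
    nb0 <- adj[s0, ]; nb0 <- nb0[nb0 > 0L]
    nb0 <- nb0[!is_node_pix[nb0]]
    path <- s0
    prev <- s0; cur <- nb0[1]
    while (!is.na(cur) && !visited[cur]) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nbc <- adj[cur, ]; nbc <- nbc[nbc > 0L]
      nxt <- nbc[!visited[nbc] & nbc != prev & !is_node_pix[nbc]]
      prev <- cur
      cur <- if (length(nxt)) nxt[1] else NA_integer_
    }
    add_edge(n_nodes, n_nodes, c(path, s0))
    remaining <- which(!is_node_pix & !visited & deg_pix > 0L &
                         node_of == 0L)
  }

  graph <- make_skeleton_graph(n_nodes, node_type, node_members, pos, nd,
                               e_from, e_to, e_len, e_paths, d, np)
  cleaned <- prune_px > 0 || spur_px > 0 || fuse_px > 0
  graph <- prune_short_branches(graph, prune_px)
  if (spur_px > 0) graph <- prune_spurs(graph, spur_px)
  if (fuse_px > 0) graph <- fuse_junctions(graph, fuse_px)
  if (cleaned) graph <- contract_pass_through(graph)
  graph
}

# Merge the two incident branches of any degree-2 node left behind by
# pruning/fusion into one: a pass-through point is not a graph node.
contract_pass_through <- function(graph) {
  repeat {
    deg <- graph$nodes$degree
    e <- graph$edges
    cand <- which(deg == 2L)
    done <- TRUE
    for (v in cand) {
      inc <- which(e$from == v | e$to == v)
      if (length(inc) != 2L) next  # self-loop node
      e1 <- inc[1]; e2 <- inc[2]
      a <- if (e$from[e1] == v) e$to[e1] else e$from[e1]
      b <- if (e$from[e2] == v) e$to[e2] else e$from[e2]
      len <- e$length_px[e1] + e$length_px[e2]
      p1 <- graph$edge_paths[[e1]]; p2 <- graph$edge_paths[[e2]]
      if (length(p1) && length(p2) && p1[1] != v && utils::tail(p1, 1) != v)
        path <- c(p1, p2) else path <- c(p1, rev(p2))
      graph$edges$from[e1] <- a
      graph$edges$to[e1] <- b
      graph$edges$length_px[e1] <- len
      graph$edges$n_slab[e1] <- e$n_slab[e1] + e$n_slab[e2] +
        graph$nodes$n_pixels[v]
      graph$edge_paths[[e1]] <- path
      graph <- drop_edges(graph, e2)
      done <- FALSE
      break
    }
    if (done) break
  }
  recount_degrees(graph)
}

#' Prune terminal spurs
#'
#' Iteratively removes branches shorter than `spur_px` that end in a free
#' (degree-1) node, artefacts of thinning wide fibre ends and ganglion
#' discs.
#'
#' @param graph a `SkeletonGraph`.
#' @param spur_px length threshold in pixels.
#' @return The pruned `SkeletonGraph`.
#' @export
prune_spurs <- function(graph, spur_px = 4) {
  if (spur_px <= 0) return(graph)
  repeat {
    e <- graph$edges
    if (!nrow(e)) break
    deg <- graph$nodes$degree
    spur <- which(e$length_px < spur_px & e$from != e$to &
                    (deg[e$from] == 1L | deg[e$to] == 1L))
    if (!length(spur)) break
    graph <- drop_edges(graph, spur)
  }
  graph
}

make_skeleton_graph <- function(n_nodes, node_type, node_members, pos, nd,
                                e_from, e_to, e_len, e_paths, d, np) {
  deg <- integer(n_nodes)
  for (i in seq_along(e_from)) {
    deg[e_from[i]] <- deg[e_from[i]] + 1L
    deg[e_to[i]] <- deg[e_to[i]] + 1L
  }
  rowc <- vapply(node_members, function(m) mean(pos[m, 1]), numeric(1))
  colc <- vapply(node_members, function(m) mean(pos[m, 2]), numeric(1))
  zc <- if (nd == 3L) vapply(node_members, function(m) mean(pos[m, 3]), numeric(1))
        else rep(NA_real_, n_nodes)
  nodes <- data.frame(id = seq_len(n_nodes), type = node_type, degree = deg,
                      row = rowc, col = colc, z = zc,
                      n_pixels = vapply(node_members, length, integer(1)))
  edges <- if (length(e_from))
    data.frame(id = seq_along(e_from), from = e_from, to = e_to,
               length_px = e_len,
               n_slab = vapply(seq_along(e_paths), function(i) {
                 p <- e_paths[[i]]
                 sum(!p %in% c(node_members[[e_from[i]]],
                               node_members[[e_to[i]]]))
               }, integer(1)))
  else data.frame(id = integer(0), from = integer(0), to = integer(0),
                  length_px = numeric(0), n_slab = integer(0))
  structure(list(nodes = nodes, edges = edges, node_pixels = node_members,
                 edge_paths = e_paths, dim = d, n_skeleton_pixels = np),
            class = "SkeletonGraph")
}

#' @export
print.SkeletonGraph <- function(x, ...) {
  cat(sprintf("SkeletonGraph: %d nodes (%d junctions), %d branches, total length %.1f px\n",
              nrow(x$nodes), sum(x$nodes$degree >= 3L), nrow(x$edges),
              sum(x$edges$length_px)))
  invisible(x)
}

recount_degrees <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  for (i in seq_len(nrow(graph$edges))) {
    deg[graph$edges$from[i]] <- deg[graph$edges$from[i]] + 1L
    deg[graph$edges$to[i]] <- deg[graph$edges$to[i]] + 1L
  }
  graph$nodes$degree <- deg
  graph
}

drop_edges <- function(graph, drop) {
  if (!length(drop)) return(graph)
  keep <- setdiff(seq_len(nrow(graph$edges)), drop)
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$edge_paths <- graph$edge_paths[keep]
  graph$edges$id <- seq_len(nrow(graph$edges))
  recount_degrees(graph)
}

#' Prune artefactual short branches
#'
#' Removes sub-`prune_px` self-loops and, among parallel branches joining
#' the same junction pair, sub-`prune_px` duplicates (the longest parallel
#' branch is kept) -- thinning artefacts at thick crossings.
#'
#' @param graph a `SkeletonGraph`.
#' @param prune_px length threshold in pixels.
#' @return The pruned `SkeletonGraph`.
#' @export
prune_short_branches <- function(graph, prune_px = 2) {
  if (prune_px <= 0 || !nrow(graph$edges)) return(graph)
  e <- graph$edges
  drop <- which(e$from == e$to & e$length_px < prune_px)
  pairkey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  dup <- which(duplicated(pairkey) | duplicated(pairkey, fromLast = TRUE))
  for (k in unique(pairkey[dup])) {
    ids <- which(pairkey == k & e$from != e$to)
    if (length(ids) < 2L) next
    short <- ids[e$length_px[ids] < prune_px]
    keep_longest <- ids[which.max(e$length_px[ids])]
    drop <- c(drop, setdiff(short, keep_longest))
  }
  drop_edges(graph, unique(drop))
}

#' Fuse junction nodes joined by short branches
#'
#' Iteratively contracts the shortest junction-junction branch below
#' `fuse_px`, merging the two junction nodes; self-loops created by a
#' contraction and shorter than `fuse_px` are removed. Restores one
#' anatomical junction where thinning split a ganglion-scale crossing into
#' nearby triple points.
#'
#' @param graph a `SkeletonGraph`.
#' @param fuse_px path-length threshold in pixels.
#' @return The fused `SkeletonGraph`.
#' @export
fuse_junctions <- function(graph, fuse_px = 6) {
  if (fuse_px <= 0) return(graph)
  repeat {
    e <- graph$edges
    if (!nrow(e)) break
    deg <- graph$nodes$degree
    cand <- which(e$from != e$to & e$length_px < fuse_px &
                    graph$nodes$type[e$from] == "junction" &
                    graph$nodes$type[e$to] == "junction")
    if (!length(cand)) break
    k <- cand[which.min(e$length_px[cand])]
    a <- e$from[k]; b <- e$to[k]
    # merge b into a
    na <- graph$nodes$n_pixels[a]; nb <- graph$nodes$n_pixels[b]
    graph$nodes$row[a] <- (graph$nodes$row[a] * na + graph$nodes$row[b] * nb) / (na + nb)
    graph$nodes$col[a] <- (graph$nodes$col[a] * na + graph$nodes$col[b] * nb) / (na + nb)
    if (!is.na(graph$nodes$z[a]))
      graph$nodes$z[a] <- (graph$nodes$z[a] * na + graph$nodes$z[b] * nb) / (na + nb)
    graph$nodes$n_pixels[a] <- na + nb
    graph$node_pixels[[a]] <- c(graph$node_pixels[[a]], graph$node_pixels[[b]])
    graph$node_pixels[[b]] <- integer(0)
    graph$edges$from[graph$edges$from == b] <- a
    graph$edges$to[graph$edges$to == b] <- a
    graph <- drop_edges(graph, k)
    # drop short self-loops created by the contraction
    e2 <- graph$edges
    loops <- which(e2$from == a & e2$to == a & e2$length_px < fuse_px)
    graph <- drop_edges(graph, loops)
  }
  recount_degrees(graph)
}

#' Junction census
#'
#' @param graph a `SkeletonGraph`.
#' @return Named integer vector: `total` (nodes of degree >= 3), `triple`
#'   (degree 3), `quadruple` (degree 4), `higher` (degree >= 5).
#' @export
junction_census <- function(graph) {
  stopifnot(inherits(graph, "SkeletonGraph"))
  deg <- graph$nodes$degree
  c(total = sum(deg >= 3L), triple = sum(deg == 3L),
    quadruple = sum(deg == 4L), higher = sum(deg >= 5L))
}

#' Branch statistics
#'
#' @param graph a `SkeletonGraph`.
#' @return Named numeric vector: `n_branches`, `total_length_px`,
#'   `mean_length_px` (NA when there are no branches).
#' @export
branch_stats <- function(graph) {
  stopifnot(inherits(graph, "SkeletonGraph"))
  n <- nrow(graph$edges)
  tot <- sum(graph$edges$length_px)
  c(n_branches = n, total_length_px = tot,
    mean_length_px = if (n > 0L) tot / n else NA_real_)
}

#' Export a skeleton graph as an edge-list data frame
#'
#' @param graph a `SkeletonGraph`.
#' @return Data frame: from, to, length_px, n_slab plus node coordinates.
#' @export
graph_edge_list <- function(graph) {
  e <- graph$edges
  data.frame(from = e$from, to = e$to, length_px = e$length_px,
             n_slab = e$n_slab,
             from_row = graph$nodes$row[e$from],
             from_col = graph$nodes$col[e$from],
             to_row = graph$nodes$row[e$to],
             to_col = graph$nodes$col[e$to])
}
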