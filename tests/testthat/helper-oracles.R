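# Independent brute-force skeleton census: per-pixel neighbour counts,
# plain flood fill for junction clusters and slab components, branch count
# as (#slab components) + (#direct node-node adjacencies). Shares no code
# with build_graph()'s branch tracer.

oracle_census <- function(sk) {
  d <- dim(sk)
  id <- matrix(0L, d[1], d[2])
  pts <- which(sk, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L)
    return(list(total = 0L, triple = 0L, quadruple = 0L, higher = 0L,
                n_branches = 0L))
  id[pts] <- seq_len(n)
  nbrs <- function(i) {
    r <- pts[i, 1]; c <- pts[i, 2]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && cc >= 1 && rr <= d[1] && cc <= d[2] && sk[rr, cc])
        out <- c(out, id[rr, cc])
    }
    out
  }
  adj <- lapply(seq_len(n), nbrs)
  deg <- lengths(adj)
  is_node <- deg != 2L          # endpoints, isolated and junction candidates
  is_junc <- deg >= 3L

  flood <- function(members, linked) {
    lab <- integer(n); nxt <- 0L
    for (i in members) {
      if (lab[i]) next
      nxt <- nxt + 1L
      q <- i; lab[i] <- nxt
      while (length(q)) {
        cur <- q[1]; q <- q[-1]
        for (j in adj[[cur]]) if (linked[j] && !lab[j]) {
          lab[j] <- nxt; q <- c(q, j)
        }
      }
    }
    lab
  }
  linked_j <- is_junc
  jlab <- flood(which(is_junc), linked_j)
  # node id per pixel: junction clusters first, then individual non-slab px
  node_of <- integer(n)
  node_of[is_junc] <- jlab[is_junc]
  n_clusters <- max(0L, jlab)
  k <- n_clusters
  for (i in which(is_node & !is_junc)) { k <- k + 1L; node_of[i] <- k }

  is_slab <- deg == 2L
  slab_lab <- flood(which(is_slab), is_slab)
  n_slab_comp <- max(0L, slab_lab)

  # degree of every node = slab-to-node adjacencies + direct node-node pairs
  node_deg <- integer(k)
  comp_touch <- rep(0L, max(n_slab_comp, 1L))
  for (i in which(is_slab)) {
    for (j in adj[[i]]) if (is_node[j]) {
      node_deg[node_of[j]] <- node_deg[node_of[j]] + 1L
      comp_touch[slab_lab[i]] <- comp_touch[slab_lab[i]] + 1L
    }
  }
  direct <- 0L
  for (i in which(is_node)) {
    for (j in adj[[i]]) {
      if (is_node[j] && j > i && node_of[j] != node_of[i]) {
        direct <- direct + 1L
        node_deg[node_of[i]] <- node_deg[node_of[i]] + 1L
        node_deg[node_of[j]] <- node_deg[node_of[j]] + 1L
      }
    }
  }
  jdeg <- node_deg[seq_len(n_clusters)]
  list(total = sum(jdeg >= 3L), triple = sum(jdeg == 3L),
       quadruple = sum(jdeg == 4L), higher = sum(jdeg >= 5L),
       n_branches = n_slab_comp + direct)
}
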