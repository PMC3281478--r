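# shared fixtures and utilities, all built in code

# random rooted binary topology without branch lengths
rand_topology <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- NULL
  tr
}

# random tip values for a tree
rand_tip_values <- function(tree, lo = 0, hi = 10) {
  stats::setNames(stats::runif(ape::Ntip(tree), lo, hi), tree$tip.label)
}

# Re-root a tree at an existing internal node, keeping the undirected edge
# set (and node count) unchanged: edges are re-oriented away from the new
# root and internal nodes renumbered to ape's convention (root = Ntip + 1).
# The old root keeps its edges and may become a unary pass-through node.
# Returns list(tree, map) with map[old_id] = new_id.
reroot_at <- function(tree, new_root) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  stopifnot(new_root > n, new_root <= m)
  adj <- vector("list", m)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, m)
  seen <- rep(FALSE, m)
  seen[new_root] <- TRUE
  queue <- new_root
  bfs <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    bfs <- c(bfs, v)
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  map <- integer(m)
  map[seq_len(n)] <- seq_len(n)
  internal_bfs <- bfs[bfs > n]
  map[internal_bfs] <- n + seq_along(internal_bfs)
  children <- which(!is.na(parent))
  edge <- cbind(map[parent[children]], map[children])
  out <- list(edge = edge, Nnode = tree$Nnode, tip.label = tree$tip.label)
  class(out) <- "phylo"
  list(tree = out, map = map)
}

# full-coverage trait table for a tree: per-limb base segment lengths plus
# optional per-species tweaks via `adjust(species, sex, limb, segment) -> mult`
make_trait_table <- function(tree, base = c(femur = 2, tibia = 3, tarsus = 4),
                             adjust = NULL) {
  grid <- expand.grid(species = tree$tip.label, sex = c("female", "male"),
                      limb = c("T1", "T2", "T3"), stringsAsFactors = FALSE)
  for (seg in names(base)) {
    vals <- rep(base[[seg]], nrow(grid))
    if (!is.null(adjust)) {
      for (i in seq_len(nrow(grid))) {
        vals[i] <- vals[i] * adjust(grid$species[i], grid$sex[i],
                                    grid$limb[i], seg)
      }
    }
    grid[[paste0(seg, "_mm")]] <- vals
  }
  as_trait_table(grid)
}

# straight horizontal landmark chain of a given length
straight_chain <- function(len, n_pts = 2) {
  cbind(seq(0, len, length.out = n_pts), 0)
}
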