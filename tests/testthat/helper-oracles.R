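# Independent oracles used across the suite.  Everything here is written
# from first principles (brute force, exhaustive enumeration, BFS) and
# deliberately avoids the package's own algorithmic code paths.

# random symmetric integer distance matrix with zero diagonal
rand_dist <- function(n, max_d = 10L, labels = paste0("h", seq_len(n))) {
  m <- matrix(0, n, n)
  vals <- sample.int(max_d, n * (n - 1L) / 2L, replace = TRUE)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  haplo_dist(m, labels = labels)
}

# threshold-scan HC oracle: smallest t in {0} U {D(x,y)} such that the
# graph with edges D <= t is connected, connectivity checked by a plain
# depth-first search
components_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

hc_scan_oracle <- function(D, Y = rownames(D)) {
  sub <- unclass(D)[Y, Y, drop = FALSE]
  if (length(Y) == 1L) return(0)
  for (t in sort(unique(c(0, sub[upper.tri(sub)])))) {
    adj <- sub <= t
    diag(adj) <- FALSE
    if (components_connected(adj)) return(t)
  }
  stop("unreachable")
}

# exhaustive HC over every k-subset (uses the scan oracle per subset)
hc_exhaustive_extrema <- function(D, k, hc_fun = hc_scan_oracle) {
  labels <- rownames(D)
  vals <- utils::combn(labels, k,
                       FUN = function(Y) hc_fun(D, Y), simplify = TRUE)
  c(min = min(vals), max = max(vals))
}

# random partially-labelled unit-edge tree as a haplo_net
rand_labelled_tree <- function(n_vertices, n_labels) {
  stopifnot(n_vertices >= 2, n_labels <= n_vertices)
  to <- seq.int(2L, n_vertices)
  from <- vapply(to, function(i) sample.int(i - 1L, 1L), integer(1))
  edges <- data.frame(vertex1 = paste0("v", from),
                      vertex2 = paste0("v", to), length = 1)
  lab_v <- paste0("v", sample.int(n_vertices, n_labels))
  haplo_net(edges, labels = stats::setNames(lab_v, paste0("L", seq_len(n_labels))))
}

# plain breadth-first-search distances on a unit-edge graph given as an
# edge data frame; returns matrix over all vertex names
bfs_distances <- function(edges) {
  verts <- unique(c(as.character(edges[[1L]]), as.character(edges[[2L]])))
  n <- length(verts)
  adj <- lapply(stats::setNames(seq_len(n), verts), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    i <- match(as.character(edges[r, 1L]), verts)
    j <- match(as.character(edges[r, 2L]), verts)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- matrix(NA_real_, n, n, dimnames = list(verts, verts))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    out[s, ] <- dist
  }
  out
}

# PD oracle 1: union of all pairwise shortest paths (edge ids via igraph)
pd_path_union_oracle <- function(net, Y) {
  g <- net$graph
  verts <- net$labels[Y]
  if (length(verts) < 2L) return(0)
  eids <- integer(0)
  for (i in seq_len(length(verts) - 1L)) {
    for (j in seq.int(i + 1L, length(verts))) {
      p <- igraph::shortest_paths(g, from = verts[i], to = verts[j],
                                  weights = igraph::E(g)$length,
                                  output = "epath")$epath[[1L]]
      eids <- union(eids, as.integer(p))
    }
  }
  sum(igraph::E(g)$length[eids])
}

# PD oracle 2 (vectorised, for exhaustive k-subset extrema): an edge lies
# in the spanning subtree of Y iff both of its deletion components
# contain a member of Y.  Returns the edge x label incidence of one side
# plus edge lengths, so PD of many subsets is a matrix product.
pd_bipartition_oracle <- function(net) {
  g <- net$graph
  m <- igraph::ecount(g)
  labs <- names(net$labels)
  side <- matrix(0L, m, length(labs), dimnames = list(NULL, labs))
  for (e in seq_len(m)) {
    h <- igraph::delete_edges(g, e)
    comp <- igraph::components(h)$membership
    ends <- igraph::ends(g, e)[1L, ]
    side[e, ] <- as.integer(comp[net$labels[labs]] == comp[[ends[1L]]])
  }
  list(side = side, len = igraph::E(g)$length)
}

pd_many <- function(bip, Ymat) {
  # Ymat: labels x subsets indicator matrix
  ina <- bip$side %*% Ymat
  tot <- matrix(colSums(Ymat), nrow(ina), ncol(ina), byrow = TRUE)
  colSums(bip$len * (ina > 0 & ina < tot))
}

# AD oracle: explicit double loop over unordered pairs
ad_loop_oracle <- function(D, Y, exponent = 2) {
  sub <- unclass(D)[Y, Y, drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) return(0)
  s <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    s <- s + sub[i, j]^exponent
    np <- np + 1L
  }
  s / np
}

ad_exhaustive_extrema <- function(D, k, exponent = 2) {
  labels <- rownames(D)
  vals <- utils::combn(labels, k, FUN = function(Y)
    ad_loop_oracle(D, Y, exponent), simplify = TRUE)
  c(min = min(vals), max = max(vals))
}
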