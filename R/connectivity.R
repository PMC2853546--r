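#' Threshold graph of a haplotype subset
#'
#' The graph `G_t(Y)` with vertex set `Y` and an edge between two distinct
#' haplotypes exactly when their distance is at most `t` (inclusive).
#' Each edge carries its distance as the weight attribute `weight`.
#' Haplotype connectivity is defined through this family of graphs: it is
#' the smallest `t` at which `G_t(Y)` becomes connected.
#'
#' @param D a [haplo_dist()] distance matrix (or coercible).
#' @param Y character vector of haplotype labels (default: all).
#' @param t non-negative threshold.
#' @return an igraph graph with vertex names `Y`, edge attribute `weight`
#'   and graph attribute `threshold`.
#' @examples
#' D <- phyletic_distances(toy_phylogeny("melting_pot"))
#' g <- threshold_graph(D, paste0("b", c(2, 4, 6, 8, 10, 12)), t = 2)
#' igraph::is_connected(g)  # FALSE: the two haplotype groups stay apart
#' @export
threshold_graph <- function(D, Y = NULL, t) {
  D <- as_haplo_dist(D)
  Y <- resolve_subset(D, Y)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("threshold t must be a single non-negative number", call. = FALSE)
  sub <- unclass(D)[Y, Y, drop = FALSE]
  adj <- (sub <= t)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g, names = TRUE)
  igraph::E(g)$weight <- if (nrow(ends)) sub[ends] else numeric(0)
  g <- igraph::set_graph_attr(g, "threshold", t)
  g
}

# Prim's algorithm on the complete graph over the labels `Y`, O(|Y|^2).
# Any minimum spanning tree is a bottleneck-minimum spanning tree, so the
# maximum edge weight of the result equals HC(Y).
prim_mst <- function(sub) {
  n <- nrow(sub)
  labels <- rownames(sub)
  if (n == 1L)
    return(list(edges = data.frame(vertex1 = character(0),
                                   vertex2 = character(0),
                                   weight = numeric(0)),
                bottleneck = 0))
  best <- sub[1L, ]        # cheapest connection of each vertex to the tree
  parent <- rep(1L, n)
  best[1L] <- NA_real_
  e1 <- integer(n - 1L)
  e2 <- integer(n - 1L)
  w <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    j <- which.min(best)
    e1[step] <- parent[j]
    e2[step] <- j
    w[step] <- best[j]
    best[j] <- NA_real_
    upd <- which(!is.na(best) & sub[j, ] < best)
    if (length(upd)) {
      best[upd] <- sub[j, upd]
      parent[upd] <- j
    }
  }
  list(edges = data.frame(vertex1 = labels[e1], vertex2 = labels[e2],
                          weight = w),
       bottleneck = max(w))
}

#' Haplotype connectivity HC(Y)
#'
#' The smallest threshold `t` such that the threshold graph `G_t(Y)` is
#' connected -- equivalently, the minimum over all spanning trees of the
#' complete distance graph on `Y` of the maximum edge weight (the
#' bottleneck value).  Low values mean the haplotypes can be linked by
#' chains of small mutational steps (a hot-spot signature); high values
#' mean some divergence gap must be crossed (a melting-pot signature).
#' `HC` of a single haplotype is 0, and for `|Y| >= 2` the value always
#' equals some pairwise distance `D(x, y)`.
#'
#' Computed as the bottleneck of an ordinary minimum spanning tree
#' (Prim's algorithm on the complete graph, O(|Y|^2)), since every MST is
#' a bottleneck-minimum spanning tree.
#'
#' @inheritParams threshold_graph
#' @return a single non-negative number.
#' @examples
#' D <- phyletic_distances(toy_phylogeny("hot_spot"))
#' haplotype_connectivity(D)  # 2: haplotypes dispersed over the phylogeny
#' @export
haplotype_connectivity <- function(D, Y = NULL) {
  D <- as_haplo_dist(D)
  Y <- resolve_subset(D, Y)
  if (length(Y) == 0L)
    stop("haplotype connectivity is undefined for an empty subset",
         call. = FALSE)
  prim_mst(unclass(D)[Y, Y, drop = FALSE])$bottleneck
}

#' Bottleneck-minimum spanning tree of a haplotype subset
#'
#' A spanning tree of the complete distance graph on `Y` whose maximum
#' edge weight equals `HC(Y)`.  Any minimum spanning tree qualifies; this
#' returns one computed by Prim's algorithm.
#'
#' @inheritParams threshold_graph
#' @return a list of class `bottleneck_mst` with components `edges` (a
#'   data frame `vertex1`, `vertex2`, `weight`) and `bottleneck`
#'   (`= HC(Y)`; 0 for a singleton, whose tree has no edges).
#' @export
bottleneck_spanning_tree <- function(D, Y = NULL) {
  D <- as_haplo_dist(D)
  Y <- resolve_subset(D, Y)
  if (length(Y) == 0L)
    stop("cannot span an empty subset", call. = FALSE)
  res <- prim_mst(unclass(D)[Y, Y, drop = FALSE])
  class(res) <- "bottleneck_mst"
  res
}

#' @export
print.bottleneck_mst <- function(x, ...) {
  cat("Bottleneck-minimum spanning tree:", nrow(x$edges) + 1L,
      "haplotypes, bottleneck =", x$bottleneck, "\n")
  if (nrow(x$edges)) print(x$edges, ...)
  invisible(x)
}

check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k))
    stop("k must be a single integer", call. = FALSE)
  if (k < 1 || k > n)
    stop("k = ", k, " out of range [1, ", n, "]", call. = FALSE)
  as.integer(k)
}

# hc_min for every k in one Kruskal-style union-find sweep.
# A k-subset with connected threshold graph at level t exists iff some
# connected component of G_t(X) has >= k vertices (prune a spanning tree
# of that component down to k vertices), so HC_min(k) is the first
# threshold at which the largest component reaches size k.
hc_min_all <- function(D) {
  sub <- unclass(D)
  n <- nrow(sub)
  out <- rep(NA_real_, n)
  out[1L] <- 0
  if (n == 1L) return(out)
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  ord <- order(sub[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  dvals <- sub[pairs]
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  reached <- 1L   # largest component size seen so far
  for (e in seq_along(dvals)) {
    a <- find(pairs[e, 1L])
    b <- find(pairs[e, 2L])
    if (a != b) {
      if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- size[a] + size[b]
      if (size[a] > reached) {
        out[seq.int(reached + 1L, size[a])] <- dvals[e]
        reached <- size[a]
      }
    }
  }
  out
}

#' Minimum haplotype connectivity over all k-subsets
#'
#' `HC_min(k)`: the smallest value of `HC(Z)` over all subsets `Z` of the
#' full haplotype set with exactly `k` elements (the bottleneck k-MST
#' problem).  Solved by a single union-find sweep over the pairwise
#' distances in increasing order: `HC_min(k)` is the first threshold at
#' which a connected component of the threshold graph on the full set
#' reaches `k` vertices.
#'
#' @inheritParams threshold_graph
#' @param k subset size, between 1 and the number of haplotypes.
#' @return a single non-negative number; `hc_min(1) = 0`.
#' @export
hc_min <- function(D, k) {
  D <- as_haplo_dist(D)
  k <- check_k(k, nrow(D))
  hc_min_all(D)[k]
}

# Shared machinery for hc_max over possibly many k: the vertex
# connectivity kappa of G_t(X) does not depend on k, so it is computed
# lazily per candidate threshold and cached.  By Menger's theorem every
# k-subset is connected at threshold t iff G_t(X) is connected and has no
# vertex separator of size <= |X| - k, i.e. kappa(G_t(X)) > |X| - k (a
# complete graph has kappa = |X| - 1 by convention, so it passes for
# every k >= 2).
hc_max_solver <- function(D) {
  n <- nrow(D)
  thresholds <- sort(unique(c(0, unclass(D)[upper.tri(D)])))
  kappa <- rep(NA_real_, length(thresholds))
  kappa_at <- function(i) {
    if (is.na(kappa[i])) {
      g <- threshold_graph(D, NULL, thresholds[i])
      kappa[i] <<- if (!igraph::is_connected(g)) 0
                   else igraph::vertex_connectivity(g)
    }
    kappa[i]
  }
  function(k) {
    if (k == 1L) return(0)
    lo <- 1L
    hi <- length(thresholds)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (kappa_at(mid) > n - k) hi <- mid else lo <- mid + 1L
    }
    thresholds[lo]
  }
}

#' Maximum haplotype connectivity over all k-subsets
#'
#' `HC_max(k)`: the largest value of `HC(Z)` over all k-element subsets.
#' It equals the smallest threshold `t` at which *every* k-subset has a
#' connected threshold graph, i.e. at which every vertex separator of
#' `G_t(X)` has more than `|X| - k` elements.  Computed by binary search
#' over the sorted distinct pairwise distances, testing at each candidate
#' threshold whether the vertex connectivity of the threshold graph on
#' the full set exceeds `|X| - k` (vertex connectivity via max-flow).
#'
#' @inheritParams hc_min
#' @return a single non-negative number; `hc_max(1) = 0`.
#' @export
hc_max <- function(D, k) {
  D <- as_haplo_dist(D)
  k <- check_k(k, nrow(D))
  hc_max_solver(D)(k)
}

#' Both connectivity extrema, for one or many subset sizes
#'
#' Computes `HC_min(k)` and `HC_max(k)` together.  The sorted pairwise
#' distances and the union-find merge sequence are computed once and
#' reused across all requested `k`, so asking for every subset size costs
#' little more than asking for one.
#'
#' @inheritParams hc_min
#' @param k integer vector of subset sizes, or `NULL` for all sizes
#'   `1..|X|`.
#' @return a data frame with columns `k`, `hc_min`, `hc_max`.
#' @examples
#' D <- phyletic_distances(toy_phylogeny("melting_pot"))
#' connectivity_bounds(D, k = c(1, 6, 13))
#' @export
connectivity_bounds <- function(D, k = NULL) {
  D <- as_haplo_dist(D)
  n <- nrow(D)
  if (is.null(k)) k <- seq_len(n)
  k <- vapply(k, check_k, integer(1), n = n)
  mins <- hc_min_all(D)
  solver <- hc_max_solver(D)
  maxs <- vapply(k, solver, numeric(1))
  data.frame(k = k, hc_min = mins[k], hc_max = maxs)
}
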