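# Rooted representation of a haplo_net tree: vertices in BFS order from
# an arbitrary root, with parent indices and the length of the edge to
# the parent.  Shared by pd() and pd_min().
rooted_tree <- function(net) {
  if (!net$is_tree)
    stop("phylogenetic diversity is only defined on trees, not cyclic ",
         "networks", call. = FALSE)
  g <- net$graph
  n <- igraph::vcount(g)
  bfs <- igraph::bfs(g, root = 1, father = TRUE)
  ord <- as.integer(bfs$order)
  parent <- as.integer(bfs$father)
  elen <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (!is.na(parent[v])) {
      eid <- igraph::get_edge_ids(g, c(parent[v], v))
      elen[v] <- igraph::E(g)$length[eid]
    }
  }
  list(order = ord, parent = parent, edge_length = elen, n = n,
       vnames = igraph::V(g)$name)
}

#' Phylogenetic diversity of a haplotype subset
#'
#' `PD(Y)`: the total edge length of the smallest subtree of the
#' phylogeny that connects all vertices labelled by elements of `Y` (the
#' Steiner subtree of the sampled vertices).  Labels may sit on interior
#' vertices as well as leaves.  `PD` of a singleton is 0; for a pair it
#' equals the phyletic distance.
#'
#' An edge belongs to the spanning subtree exactly when both components
#' obtained by deleting it contain a member of `Y`, so `PD` is computed
#' by one postorder sweep counting members of `Y` below each edge.
#'
#' @param phylogeny a [haplo_net()] **tree** (or ape `phylo`).
#' @param Y haplotype labels (default: all sampled haplotypes).
#' @return total subtree length (same units as the edge lengths).
#' @examples
#' net <- toy_phylogeny("hot_spot")
#' pd(net, c("a1", "a13")) == phyletic_distances(net)["a1", "a13"]
#' @export
pd <- function(phylogeny, Y = NULL) {
  net <- as_haplo_net(phylogeny)
  if (is.null(Y)) Y <- names(net$labels)
  Y <- unique(as.character(Y))
  unknown <- setdiff(Y, names(net$labels))
  if (length(unknown))
    stop("unknown haplotype label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(Y) == 0L)
    stop("PD is undefined for an empty subset", call. = FALSE)
  rt <- rooted_tree(net)
  in_y <- rt$vnames %in% net$labels[Y]
  below <- as.integer(in_y)
  for (v in rev(rt$order)) {
    if (!is.na(rt$parent[v])) below[rt$parent[v]] <- below[rt$parent[v]] + below[v]
  }
  total <- sum(in_y)
  on_path <- below > 0L & below < total & !is.na(rt$parent)
  sum(rt$edge_length[on_path])
}

#' Minimum phylogenetic diversity over all k-subsets
#'
#' `PD_min(k)`: the smallest `PD(Y)` over all k-element subsets of the
#' sampled haplotypes.  Solved exactly by dynamic programming over the
#' tree (the i-tree recursion): rooting arbitrarily, `cost[v][j]` is the
#' minimal total length of a connected subtree that contains vertex `v`,
#' lies below `v`, and covers exactly `j` sampled vertices; children are
#' folded in knapsack-style, and the answer is the minimum over all
#' vertices `v` and all `j >= k` (a connected subtree covering more than
#' `k` sampled vertices also yields a k-subset at no extra length).
#'
#' @inheritParams pd
#' @param k subset size, between 1 and the number of sampled haplotypes.
#' @return minimal subtree length; `pd_min(1) = 0`.
#' @export
pd_min <- function(phylogeny, k) {
  net <- as_haplo_net(phylogeny)
  nlab <- length(net$labels)
  k <- check_k(k, nlab)
  if (k == 1L) return(0)
  rt <- rooted_tree(net)
  labelled <- rt$vnames %in% net$labels
  # children lists
  kids <- vector("list", rt$n)
  for (v in seq_len(rt$n)) {
    p <- rt$parent[v]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  # cost[[v]] indexed 1..(nlab+1) for j = 0..nlab
  cost <- vector("list", rt$n)
  best <- Inf
  for (v in rev(rt$order)) {
    dp <- rep(Inf, nlab + 1L)
    dp[1L + labelled[v]] <- 0
    for (ch in kids[[v]]) {
      cdp <- cost[[ch]] + rt$edge_length[ch]
      ndp <- dp
      for (j in which(is.finite(dp))) {
        add <- dp[j] + cdp
        improved <- which(add < ndp[seq_along(cdp) + j - 1L])
        if (length(improved))
          ndp[improved + j - 1L] <- add[improved]
      }
      dp <- ndp[seq_len(nlab + 1L)]
    }
    cost[[v]] <- dp
    best <- min(best, dp[seq.int(k + 1L, nlab + 1L)])
  }
  best
}

#' Maximum phylogenetic diversity over all k-subsets
#'
#' `PD_max(k)`: the largest `PD(Y)` over all k-element subsets, computed
#' by the greedy chain that is provably optimal for PD maximisation on
#' trees: start from the pair of sampled haplotypes at maximal phyletic
#' distance, then repeatedly add the haplotype whose distance to the
#' current subtree is largest.
#'
#' @inheritParams pd_min
#' @return maximal subtree length; `pd_max(1) = 0`, and `pd_max(2)` is
#'   the phyletic diameter of the sampled haplotypes.
#' @export
pd_max <- function(phylogeny, k) {
  net <- as_haplo_net(phylogeny)
  nlab <- length(net$labels)
  k <- check_k(k, nlab)
  if (k == 1L) return(0)
  g <- net$graph
  wl <- igraph::E(g)$length
  lab_v <- match(net$labels, igraph::V(g)$name)
  dv <- igraph::distances(g, weights = wl)   # all-pairs vertex distances
  dl <- dv[lab_v, lab_v, drop = FALSE]
  start <- which(dl == max(dl), arr.ind = TRUE)[1L, ]
  total <- dl[start[1L], start[2L]]
  path <- igraph::shortest_paths(g, from = lab_v[start[1L]],
                                 to = lab_v[start[2L]], weights = wl)$vpath[[1L]]
  tree_v <- as.integer(path)
  chosen <- c(start[1L], start[2L])
  while (length(chosen) < k) {
    remaining <- setdiff(seq_len(nlab), chosen)
    inc <- vapply(remaining,
                  function(i) min(dv[lab_v[i], tree_v]), numeric(1))
    pick <- remaining[which.max(inc)]
    total <- total + max(inc)
    nearest <- tree_v[which.min(dv[lab_v[pick], tree_v])]
    path <- igraph::shortest_paths(g, from = lab_v[pick], to = nearest,
                                   weights = wl)$vpath[[1L]]
    tree_v <- union(tree_v, as.integer(path))
    chosen <- c(chosen, pick)
  }
  total
}

#' Average (squared) pairwise distance of a haplotype subset
#'
#' `AD(Y)`: the mean of `D(x, y)^p` over all unordered pairs in `Y`.  The
#' exponent defaults to `p = 2` (average squared pairwise distance); set
#' `exponent = 1` for the plain average pairwise distance.  `AD` of a
#' singleton is defined as 0.
#'
#' @inheritParams threshold_graph
#' @param exponent power applied to each pairwise distance (2 or 1).
#' @return a single non-negative number.
#' @export
ad <- function(D, Y = NULL, exponent = 2) {
  D <- as_haplo_dist(D)
  Y <- resolve_subset(D, Y)
  if (length(Y) < 2L) return(0)
  sub <- unclass(D)[Y, Y, drop = FALSE]
  mean(sub[upper.tri(sub)]^exponent)
}

ad_enumerate <- function(V, k, mode) {
  n <- nrow(V)
  sums <- utils::combn(n, k, FUN = function(idx) sum(V[idx, idx]) / 2)
  if (mode == "min") min(sums) else max(sums)
}

# Best-sum branch and bound for the MAXISUM / MINISUM dispersion problem:
# choose k of n points extremising the sum of pairwise values V.  The
# bound for a partial selection S with r slots left combines each
# candidate's cross-sum into S with an extremal estimate of the
# candidate-candidate pairs.
ad_branch_bound <- function(V, k, mode) {
  n <- nrow(V)
  sign <- if (mode == "max") 1 else -1
  W <- sign * V                       # always maximise
  # greedy incumbent
  ut <- which(upper.tri(W), arr.ind = TRUE)
  idx <- ut[which.max(W[ut]), ]
  S <- as.integer(idx)
  while (length(S) < k) {
    rem <- setdiff(seq_len(n), S)
    gain <- vapply(rem, function(j) sum(W[j, S]), numeric(1))
    S <- c(S, rem[which.max(gain)])
  }
  best <- sum(W[S, S]) / 2
  recurse <- function(S, i, cur) {
    r <- k - length(S)
    if (r == 0L) {
      if (cur > best) best <<- cur
      return(invisible())
    }
    if (i > n || n - i + 1L < r) return(invisible())
    cand <- seq.int(i, n)
    wmax <- if (length(cand) > 1L) max(W[cand, cand][upper.tri(diag(length(cand)))]) else 0
    score <- vapply(cand, function(j)
      (if (length(S)) sum(W[j, S]) else 0) + (r - 1) / 2 * wmax, numeric(1))
    ub <- cur + sum(sort(score, decreasing = TRUE)[seq_len(r)])
    if (ub < best || isTRUE(all.equal(ub, best))) return(invisible())
    j <- cand[1L]
    recurse(c(S, j), i + 1L, cur + (if (length(S)) sum(W[j, S]) else 0))
    recurse(S, i + 1L, cur)
  }
  recurse(integer(0), 1L, 0)
  sign * best
}

#' Exact extrema of AD over all k-subsets
#'
#' `AD_min(k)` / `AD_max(k)`: the exact minimum or maximum of [ad()] over
#' all k-element subsets of the full haplotype set.  Both problems are
#' NP-hard (the maximisation is the MAXISUM facility-dispersion problem),
#' so only exact search is offered: exhaustive enumeration for small sets
#' and a best-first branch and bound with pairwise-sum bounds up to a
#' hard cap.  Above the cap a capacity error is raised rather than
#' silently approximating.
#'
#' @inheritParams ad
#' @param k subset size (2..|X|).
#' @param mode `"min"` or `"max"`.
#' @param method `"auto"` picks enumeration below `exhaustive_limit`
#'   haplotypes and branch and bound up to `cap`.
#' @param exhaustive_limit switch-over size for plain enumeration.
#' @param cap hard limit on |X| for exact search.
#' @return the extremal AD value (already divided by `choose(k, 2)`).
#' @export
ad_extrema <- function(D, k, mode = c("min", "max"), exponent = 2,
                       method = c("auto", "exhaustive", "branch-and-bound"),
                       exhaustive_limit = 16, cap = 25) {
  D <- as_haplo_dist(D)
  mode <- match.arg(mode)
  method <- match.arg(method)
  n <- nrow(D)
  k <- check_k(k, n)
  if (k < 2L)
    stop("AD extrema need subset size k >= 2", call. = FALSE)
  if (method == "auto")
    method <- if (n < exhaustive_limit) "exhaustive" else "branch-and-bound"
  if (method == "branch-and-bound" && n > cap)
    stop("exact AD extrema are capped at ", cap, " haplotypes (NP-hard ",
         "problem); analyse a subset or raise `cap`", call. = FALSE)
  V <- unclass(D)^exponent
  s <- switch(method,
              "exhaustive" = ad_enumerate(V, k, mode),
              "branch-and-bound" = ad_branch_bound(V, k, mode))
  s / choose(k, 2)
}

#' Genetic diversity spectrum
#'
#' The frequency distribution of the pairwise distances within a
#' haplotype subset: for every observed distance, the number of haplotype
#' pairs exactly that far apart.  A bimodal spectrum (many small and many
#' large distances, few in between) is the signature of two divergent
#' haplotype clusters, as expected in a melting-pot.  Counts always sum
#' to `choose(|Y|, 2)`.
#'
#' @inheritParams threshold_graph
#' @param bin_width optional bin width for non-integer distances; by
#'   default every distinct value gets its own count.
#' @return a data frame of class `gds` with columns `distance` and
#'   `count`.
#' @export
gds <- function(D, Y = NULL, bin_width = NULL) {
  D <- as_haplo_dist(D)
  Y <- resolve_subset(D, Y)
  if (length(Y) < 2L) {
    warning("genetic diversity spectrum of a singleton is empty")
    out <- data.frame(distance = numeric(0), count = integer(0))
    class(out) <- c("gds", class(out))
    return(out)
  }
  sub <- unclass(D)[Y, Y, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  if (!is.null(bin_width)) vals <- floor(vals / bin_width) * bin_width
  tab <- table(vals)
  out <- data.frame(distance = as.numeric(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gds", class(out))
  out
}
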