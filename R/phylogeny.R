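#' Haplotype phylogeny or network
#'
#' A `haplo_net` holds a connected graph whose vertices are haplotype
#' states: *sampled* vertices carry a haplotype label, the remaining
#' vertices are hypothetical (unsampled or extinct) intermediates.  Edges
#' carry positive lengths in mutational steps (or substitutions).  Trees
#' are the common case -- and the only case on which phylogenetic
#' diversity is defined -- but cyclic haplotype networks (as produced by
#' statistical parsimony) are accepted for phyletic distances, which then
#' use shortest paths.
#'
#' @param edges two- or three-column data frame (`vertex1`, `vertex2`,
#'   optional `length`); absent lengths default to 1.
#' @param labels named character vector mapping haplotype label to vertex
#'   id (`c(h1 = "v3", ...)`).  A vertex may carry at most one label.  If
#'   `NULL`, every vertex is taken as sampled and labelled by its own id.
#' @return an object of class `haplo_net` with components `graph` (an
#'   igraph with edge attribute `length`), `labels` (haplotype -> vertex
#'   map) and `is_tree`.
#' @examples
#' net <- haplo_net(data.frame(vertex1 = c("u", "u"), vertex2 = c("v", "w")),
#'                  labels = c(x = "v", y = "w"))
#' net$is_tree
#' @export
haplo_net <- function(edges, labels = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L)
    stop("edge list needs at least two columns (vertex1, vertex2)",
         call. = FALSE)
  v1 <- as.character(edges[[1L]])
  v2 <- as.character(edges[[2L]])
  len <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(v1))
  len[is.na(len)] <- 1
  if (any(len <= 0))
    stop("edge lengths must be positive", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = v1, to = v2, length = len),
    directed = FALSE
  )
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    stop("edge list contains loops or duplicate edges", call. = FALSE)
  if (!igraph::is_connected(g))
    stop("haplotype phylogeny/network must be connected", call. = FALSE)
  verts <- igraph::V(g)$name
  if (is.null(labels)) {
    labels <- stats::setNames(verts, verts)
  } else {
    labels <- stats::setNames(as.character(labels), names(labels))
    if (is.null(names(labels)) || any(!nzchar(names(labels))))
      stop("labels must be a named vector (haplotype label -> vertex)",
           call. = FALSE)
    if (anyDuplicated(names(labels)))
      stop("duplicate haplotype labels", call. = FALSE)
    if (anyDuplicated(labels))
      stop("a vertex may carry at most one haplotype label", call. = FALSE)
    unknown <- setdiff(labels, verts)
    if (length(unknown))
      stop("labelled vertices not in graph: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(labels) < 1L)
    stop("phylogeny must carry at least one haplotype label", call. = FALSE)
  structure(
    list(graph = g, labels = labels,
         is_tree = igraph::ecount(g) == igraph::vcount(g) - 1L),
    class = "haplo_net"
  )
}

#' @export
print.haplo_net <- function(x, ...) {
  cat("Haplotype ", if (x$is_tree) "phylogeny (tree)" else "network (cyclic)",
      ": ", igraph::vcount(x$graph), " vertices (",
      length(x$labels), " sampled haplotypes, ",
      igraph::vcount(x$graph) - length(x$labels),
      " hypothetical), total length ",
      format(total_length(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname haplo_net
#' @param x a `haplo_net`.
#' @export
total_length <- function(x) {
  stopifnot(inherits(x, "haplo_net"))
  sum(igraph::E(x$graph)$length)
}

#' @rdname haplo_net
#' @export
haplotype_labels <- function(x) {
  stopifnot(inherits(x, "haplo_net"))
  names(x$labels)
}

#' Convert an ape "phylo" tree into a haplotype phylogeny
#'
#' Tips are always sampled haplotypes; interior nodes with a non-empty
#' node label are treated as sampled haplotypes too (haplotype phylogenies
#' routinely place observed haplotypes at interior vertices).  Missing
#' branch lengths default to 1 with a warning, matching the unit-edge
#' convention of mutational-step networks.
#'
#' @param phy an [ape::read.tree()] style `phylo` object.
#' @return a [haplo_net()].
#' @export
as_haplo_net <- function(phy) {
  if (inherits(phy, "haplo_net")) return(phy)
  if (!inherits(phy, "phylo"))
    stop("expected an ape 'phylo' tree or a haplo_net", call. = FALSE)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  vnames <- character(ntip + nnode)
  vnames[seq_len(ntip)] <- phy$tip.label
  inner <- if (!is.null(phy$node.label)) phy$node.label else character(nnode)
  inner[is.na(inner)] <- ""
  for (i in seq_len(nnode)) {
    vnames[ntip + i] <- if (nzchar(inner[i])) inner[i] else paste0(".node", i)
  }
  if (anyDuplicated(vnames))
    stop("duplicate vertex labels in tree", call. = FALSE)
  len <- phy$edge.length
  if (is.null(len)) {
    warning("tree has no branch lengths; defaulting every edge to length 1")
    len <- rep(1, nrow(phy$edge))
  }
  edges <- data.frame(vertex1 = vnames[phy$edge[, 1L]],
                      vertex2 = vnames[phy$edge[, 2L]],
                      length = len)
  sampled <- c(phy$tip.label,
               vnames[ntip + which(nzchar(inner))])
  haplo_net(edges, labels = stats::setNames(sampled, sampled))
}

#' Phyletic distances between sampled haplotypes
#'
#' The path-length distance measured along the phylogeny or network: on a
#' tree the (unique) path between the two labelled vertices, on a cyclic
#' network the shortest path.  Path length is the sum of edge lengths, so
#' on a unit-edge phylogeny it is the number of edges (mutational steps)
#' separating two haplotypes.
#'
#' @param phylogeny a [haplo_net()], or an ape `phylo` tree.
#' @return a [haplo_dist()] on the sampled haplotype labels.
#' @examples
#' net <- toy_phylogeny("hot_spot")
#' phyletic_distances(net)["a1", "a2"]
#' @export
phyletic_distances <- function(phylogeny) {
  net <- as_haplo_net(phylogeny)
  d <- igraph::distances(net$graph, v = net$labels, to = net$labels,
                         weights = igraph::E(net$graph)$length)
  dimnames(d) <- list(names(net$labels), names(net$labels))
  haplo_dist(d, symmetrize = TRUE)
}
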