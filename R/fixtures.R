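#' Packaged toy haplotype phylogenies
#'
#' Two small unit-edge haplotype phylogenies on 13 sampled haplotypes
#' each, illustrating the two ways a region can come by high genetic
#' diversity:
#'
#' * `"hot_spot"` -- haplotypes `a1..a13` dispersed along the phylogeny,
#'   every haplotype within two mutational steps of another one;
#'   haplotype connectivity of the full set is 2.
#' * `"melting_pot"` -- haplotypes `b1..b13` clumped into two divergent
#'   groups joined only through unsampled (hypothetical) intermediates;
#'   haplotype connectivity of the full set is 5.
#'
#' Both trees have the same total length, so classical diversity measures
#' cannot tell the scenarios apart -- connectivity can.  Shipped as
#' edge-list + label-map TSV under `inst/extdata`.
#'
#' @param scenario `"hot_spot"` or `"melting_pot"`.
#' @return a [haplo_net()].
#' @examples
#' haplotype_connectivity(phyletic_distances(toy_phylogeny("hot_spot")))
#' @export
toy_phylogeny <- function(scenario = c("hot_spot", "melting_pot")) {
  scenario <- match.arg(scenario)
  stem <- if (scenario == "hot_spot") "toy_hotspot" else "toy_meltingpot"
  edges <- utils::read.delim(
    system.file("extdata", paste0(stem, "_edges.tsv"), package = "hapconn"))
  labmap <- utils::read.delim(
    system.file("extdata", paste0(stem, "_labels.tsv"), package = "hapconn"))
  haplo_net(edges, labels = stats::setNames(as.character(labmap$vertex),
                                            labmap$haplotype))
}

#' Published per-region score tables from the two case studies
#'
#' The summary score tables of the two published applications of the
#' method: six geographic regions of a *Brachyderes rugatus* beetle
#' population on La Palma (PD-based diversity, phyletic distances on a
#' 69-haplotype mtDNA network), and ten Mediterranean sampling locations
#' of *Pinus pinaster* (AD-based diversity, allele-size distances on 34
#' chloroplast microsatellite haplotypes).  The underlying sequence and
#' distance data are not available in machine-readable form, so these
#' tables carry the published raw, minimum, maximum and normalized values
#' only; they are used to check the normalization arithmetic.
#'
#' @param study `"beetle"` or `"pine"`.
#' @return a data frame mirroring the published table.
#' @export
published_scores <- function(study = c("beetle", "pine")) {
  study <- match.arg(study)
  file <- if (study == "beetle") "beetle_region_scores.tsv"
          else "pine_location_scores.tsv"
  utils::read.delim(system.file("extdata", file, package = "hapconn"))
}

# grow a random unit-edge tree by sequential uniform attachment;
# returns edge data frame on vertices prefix1..prefixN
grow_tree <- function(n_vertices, prefix = "v") {
  stopifnot(n_vertices >= 1)
  if (n_vertices == 1L)
    return(data.frame(vertex1 = character(0), vertex2 = character(0),
                      length = numeric(0)))
  to <- seq.int(2L, n_vertices)
  from <- vapply(to, function(i) sample.int(i - 1L, 1L), integer(1))
  data.frame(vertex1 = paste0(prefix, from), vertex2 = paste0(prefix, to),
             length = 1)
}

#' Simulate a hot-spot-like or melting-pot-like haplotype dataset
#'
#' Generates a random unit-edge haplotype phylogeny with partially
#' labelled vertices, its phyletic distance matrix, and a region table
#' with one focal region, emulating the two structures the connectivity
#' score is designed to distinguish:
#'
#' * `"hot_spot"`: one random tree grown by sequential uniform
#'   attachment, with sampled haplotypes spread uniformly over its
#'   vertices -- in-situ diversification leaves the sampled haplotypes
#'   dispersed.
#' * `"melting_pot"`: `n_clusters` such trees joined by paths of
#'   unlabelled (hypothetical, i.e. extinct or unsampled) vertices of
#'   length `separation`, with sampled haplotypes confined to the
#'   clusters -- secondary contact of divergent gene pools.  Any path
#'   between clusters crosses the unlabelled bridge, so cross-cluster
#'   haplotypes are at least `separation` steps apart.
#'
#' In both scenarios the tree has `n_vertices` vertices and hence total
#' length `n_vertices - 1`: scenarios with the same `n_vertices` are
#' matched in total tree length, so raw diversity alone cannot separate
#' them.  The focal region samples `focal_size` haplotypes (stratified
#' across clusters in the melting-pot, so it genuinely mixes the gene
#' pools); remaining haplotypes form a `"background"` region.
#'
#' @param scenario `"hot_spot"` or `"melting_pot"`.
#' @param n_haplotypes number of sampled (labelled) haplotypes.
#' @param n_vertices total vertices in the phylogeny (>= n_haplotypes;
#'   fixes total tree length at `n_vertices - 1`).
#' @param n_clusters number of divergent clusters (melting-pot only).
#' @param separation length of the unlabelled bridge between consecutive
#'   clusters, in mutational steps; must exceed the within-cluster spread
#'   of the sampled haplotypes for a clear melting-pot signal.
#' @param label_radius melting-pot only: sampled haplotypes are placed
#'   within this path distance of their cluster root (`Inf`: anywhere in
#'   the cluster).  Use a small radius to bound the within-cluster
#'   spread.
#' @param focal_size haplotypes in the focal region (default: half,
#'   rounded up).
#' @param seed integer seed; the seed fully determines the output.
#' @return list with components `phylogeny` ([haplo_net()]), `distances`
#'   ([haplo_dist()] of phyletic distances), `regions`
#'   ([region_table()]), `scenario`, `seed`.
#' @examples
#' sim <- simulate_scenario("melting_pot", seed = 42)
#' haplotype_connectivity(sim$distances, sim$regions$focal)
#' @export
simulate_scenario <- function(scenario = c("hot_spot", "melting_pot"),
                              n_haplotypes = 12, n_vertices = 30,
                              n_clusters = 2, separation = 10,
                              label_radius = Inf,
                              focal_size = ceiling(n_haplotypes / 2),
                              seed = NULL) {
  scenario <- match.arg(scenario)
  if (n_haplotypes < 2L)
    stop("need at least two haplotypes", call. = FALSE)
  if (n_vertices < n_haplotypes)
    stop("cannot place ", n_haplotypes, " labels on ", n_vertices,
         " vertices", call. = FALSE)
  if (focal_size < 1L || focal_size > n_haplotypes)
    stop("focal_size out of range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (scenario == "hot_spot") {
    edges <- grow_tree(n_vertices)
    verts <- paste0("v", seq_len(n_vertices))
    lab_verts <- sample(verts, n_haplotypes)
    labels <- stats::setNames(lab_verts, paste0("h", seq_len(n_haplotypes)))
    net <- haplo_net(edges, labels = labels)
    focal <- sample(names(labels), focal_size)
  } else {
    if (n_clusters < 2L)
      stop("a melting-pot needs at least two clusters", call. = FALSE)
    if (separation < 2L)
      stop("separation must be at least 2 so that the bridge contains ",
           "an unlabelled intermediate", call. = FALSE)
    n_bridge <- (n_clusters - 1L) * (separation - 1L)
    n_cluster_total <- n_vertices - n_bridge
    csize <- diff(round(seq(0, n_cluster_total, length.out = n_clusters + 1L)))
    if (any(csize < 1L))
      stop("n_vertices too small for ", n_clusters, " clusters with ",
           "separation ", separation, call. = FALSE)
    nlab <- diff(round(seq(0, n_haplotypes, length.out = n_clusters + 1L)))
    if (any(nlab < 1L))
      stop("each cluster needs at least one sampled haplotype", call. = FALSE)
    if (any(nlab > csize))
      stop("cannot place ", max(nlab), " labels in a cluster of ",
           min(csize), " vertices", call. = FALSE)
    edges <- NULL
    lab_verts <- character(0)
    cluster_of <- integer(0)
    for (ci in seq_len(n_clusters)) {
      pre <- paste0("c", ci, "v")
      ed <- grow_tree(csize[ci], prefix = pre)
      edges <- rbind(edges, ed)
      # bridge from previous cluster root to this one
      if (ci > 1L) {
        bridge <- c(paste0("c", ci - 1L, "v1"),
                    if (separation > 1L)
                      paste0("b", ci - 1L, "_", seq_len(separation - 1L)),
                    paste0(pre, 1L))
        edges <- rbind(edges, data.frame(
          vertex1 = bridge[-length(bridge)], vertex2 = bridge[-1L],
          length = 1))
      }
      # candidate label positions within label_radius of the cluster root
      cverts <- paste0(pre, seq_len(csize[ci]))
      if (is.finite(label_radius) && csize[ci] > 1L) {
        g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                           vertices = cverts)
        droot <- igraph::distances(g, v = paste0(pre, 1L))[1L, cverts]
        cand <- cverts[droot <= label_radius]
      } else cand <- cverts
      if (length(cand) < nlab[ci])
        stop("label_radius ", label_radius, " leaves only ", length(cand),
             " candidate vertices for ", nlab[ci], " labels", call. = FALSE)
      picked <- if (length(cand) == 1L) cand else sample(cand, nlab[ci])
      lab_verts <- c(lab_verts, picked)
      cluster_of <- c(cluster_of, rep(ci, nlab[ci]))
    }
    labels <- stats::setNames(lab_verts, paste0("h", seq_along(lab_verts)))
    net <- haplo_net(edges, labels = labels)
    # stratified focal sample: every cluster contributes
    share <- diff(round(seq(0, focal_size, length.out = n_clusters + 1L)))
    if (any(share < 1L))
      stop("focal_size too small to span ", n_clusters, " clusters",
           call. = FALSE)
    focal <- unlist(lapply(seq_len(n_clusters), function(ci) {
      pool <- names(labels)[cluster_of == ci]
      if (length(pool) == 1L) pool else sample(pool, min(share[ci], length(pool)))
    }), use.names = FALSE)
  }

  regs <- list(focal = focal)
  rest <- setdiff(names(labels), focal)
  if (length(rest)) regs$background <- rest
  list(phylogeny = net,
       distances = phyletic_distances(net),
       regions = region_table(regs),
       scenario = scenario, seed = seed)
}
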