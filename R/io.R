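#' Read an aligned FASTA file of haplotype sequences
#'
#' Labels are the record identifiers up to the first whitespace.
#' Sequences are returned uppercase; alignment gaps are preserved.
#'
#' @param path FASTA file of aligned DNA haplotypes.
#' @return named character vector of sequences, ready for
#'   [hamming_distances()].
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path, call. = FALSE)
  seqs <- toupper(vapply(as.character(dna), paste, character(1),
                         collapse = ""))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a Newick tree as a haplotype phylogeny
#'
#' Tips -- and interior nodes that carry a label -- become sampled
#' haplotypes; unlabelled interior nodes are hypothetical intermediates.
#' Missing branch lengths default to 1 (the unit-edge mutational-step
#' convention) with a warning.
#'
#' @param path Newick file.
#' @return a [haplo_net()].
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file ", path, call. = FALSE)
  as_haplo_net(phy)
}

#' Read a haplotype network from an edge-list TSV
#'
#' @param path TSV with columns `vertex1`, `vertex2` and optional
#'   `length` (default 1).
#' @param label_map optional TSV with columns `vertex`, `haplotype`
#'   mapping vertices to sampled-haplotype labels; without it every
#'   vertex is taken as sampled.
#' @return a [haplo_net()].
#' @export
read_edge_list <- function(path, label_map = NULL) {
  edges <- utils::read.delim(path, check.names = FALSE)
  labels <- NULL
  if (!is.null(label_map)) {
    lm <- utils::read.delim(label_map, check.names = FALSE)
    if (ncol(lm) < 2L)
      stop("label map needs columns vertex, haplotype", call. = FALSE)
    labels <- stats::setNames(as.character(lm[[1L]]), as.character(lm[[2L]]))
  }
  haplo_net(edges, labels = labels)
}

#' Read microsatellite allele profiles
#'
#' @param path TSV: first column haplotype ID, remaining columns integer
#'   allele sizes (one per locus, identical locus set for all rows).
#' @return numeric matrix (rows = haplotypes) for
#'   [allele_size_distances()].
#' @export
read_allele_profiles <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("allele profile table needs an ID column plus >= 1 locus",
         call. = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric allele sizes in ", path, call. = FALSE)
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Read a region-assignment table
#'
#' @param path TSV with columns `haplotype_id`, `region` (one row per
#'   occurrence).
#' @return a [region_table()].
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  region_table(tab)
}

split_tokens <- function(line) strsplit(trimws(line), "[ \t]+")[[1L]]

parse_phylip <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("line 1 of ", path, ": expected a taxon count", call. = FALSE)
  if (length(lines) != n + 1L)
    stop(path, ": expected ", n, " matrix rows, found ", length(lines) - 1L,
         call. = FALSE)
  rows <- lapply(lines[-1L], split_tokens)
  counts <- lengths(rows)
  labels <- vapply(rows, `[`, character(1), 1L)
  M <- matrix(0, n, n)
  if (all(counts == n + 1L)) {            # square dialect
    for (i in seq_len(n)) {
      vals <- suppressWarnings(as.numeric(rows[[i]][-1L]))
      if (anyNA(vals))
        stop("line ", i + 1L, " of ", path, ": non-numeric distance",
             call. = FALSE)
      M[i, ] <- vals
    }
  } else if (all(counts == seq_len(n))) { # lower-triangular dialect
    for (i in seq_len(n)) {
      if (i == 1L) next
      vals <- suppressWarnings(as.numeric(rows[[i]][-1L]))
      if (anyNA(vals))
        stop("line ", i + 1L, " of ", path, ": non-numeric distance",
             call. = FALSE)
      M[i, seq_len(i - 1L)] <- vals
      M[seq_len(i - 1L), i] <- vals
    }
  } else {
    stop(path, ": rows match neither the square (", n + 1L,
         " fields) nor the lower-triangular dialect", call. = FALSE)
  }
  haplo_dist(M, labels = labels)
}

parse_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(path, ": non-numeric entries in distance matrix", call. = FALSE)
  storage.mode(m) <- "double"
  if (!identical(colnames(m), labels))
    stop(path, ": column labels do not match row labels", call. = FALSE)
  haplo_dist(m, labels = labels)
}

#' Read a distance matrix file
#'
#' Supports relaxed PHYLIP (square and lower-triangular dialects;
#' whitespace-separated, no fixed-width name padding required) and plain
#' TSV (header of labels, first column labels).  `dialect = "auto"`
#' detects PHYLIP by its leading taxon-count line.
#'
#' @param path matrix file.
#' @param dialect `"auto"`, `"phylip-square"`, `"phylip-lower"` or
#'   `"tsv"`.
#' @return a [haplo_dist()].
#' @export
read_distances <- function(path,
                           dialect = c("auto", "phylip-square",
                                       "phylip-lower", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(split_tokens(first)) == 1L &&
                   !is.na(suppressWarnings(as.integer(trimws(first)))))
      "phylip" else "tsv"
  }
  if (dialect == "tsv") return(parse_matrix_tsv(path))
  parse_phylip(readLines(path), path)
}

fmt_num <- function(x) {
  # full-precision decimal text so that write/read round-trips exactly
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else formatC(v, digits = 17, format = "g")
  }, character(1))
}

#' Write a distance matrix
#'
#' `"tsv"` writes a labelled square matrix that [read_distances()] reads
#' back bit-identically.  `"phylip"` / `"phylip-lower"` write strict
#' PHYLIP with names padded to 10 characters (longer labels are
#' rejected rather than truncated).
#'
#' @param D a [haplo_dist()].
#' @param path output file.
#' @param format `"tsv"`, `"phylip"` or `"phylip-lower"`.
#' @export
write_distances <- function(D, path, format = c("tsv", "phylip",
                                                "phylip-lower")) {
  D <- as_haplo_dist(D)
  format <- match.arg(format)
  labels <- rownames(D)
  n <- nrow(D)
  if (format == "tsv") {
    lines <- c(paste(c("label", labels), collapse = "\t"),
               vapply(seq_len(n), function(i)
                 paste(c(labels[i], fmt_num(unclass(D)[i, ])),
                       collapse = "\t"), character(1)))
  } else {
    if (any(nchar(labels) > 10L))
      stop("PHYLIP limits names to 10 characters; offending label(s): ",
           paste(labels[nchar(labels) > 10L], collapse = ", "),
           call. = FALSE)
    pad <- formatC(labels, width = -10)
    lines <- sprintf("%5d", n)
    for (i in seq_len(n)) {
      vals <- if (format == "phylip") unclass(D)[i, ]
              else unclass(D)[i, seq_len(i - 1L), drop = TRUE]
      lines <- c(lines, trimws(paste(c(pad[i], fmt_num(vals)),
                                     collapse = "  "), which = "right"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a spanning tree as an edge-list TSV
#'
#' @param tree a [bottleneck_spanning_tree()] result.
#' @param path output TSV (`vertex1`, `vertex2`, `weight`).
#' @export
write_spanning_tree <- function(tree, path) {
  stopifnot(inherits(tree, "bottleneck_mst"))
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a region score table
#'
#' @param rows a [score_regions()] result (possibly annotated by
#'   [interpret_regions()]).
#' @param path output file.
#' @param digits decimal places for the TSV (half-up rounding, matching
#'   conventional table display); ignored for JSON, which always carries
#'   full precision.
#' @param json write JSON instead of TSV.
#' @export
write_scores <- function(rows, path, digits = 2, json = FALSE) {
  out <- as.data.frame(rows)
  if (json) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
    out[num] <- lapply(out[num], function(v)
      formatC(round_half_up(v, digits), format = "f", digits = digits))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
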