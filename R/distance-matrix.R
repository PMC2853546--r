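#' Validate (or construct) a haplotype distance matrix
#'
#' A `haplo_dist` object is a square numeric matrix of pairwise genetic
#' distances between haplotypes: symmetric, zero on the diagonal, all
#' entries finite and non-negative.  Row/column names carry the haplotype
#' labels and fix the haplotype order.  Every front-end constructor
#' ([hamming_distances()], [allele_size_distances()],
#' [phyletic_distances()]) and every matrix reader funnels through this
#' validator, so downstream code (connectivity, diversity, scoring) can
#' assume the invariants hold.  No triangle inequality is required:
#' the connectivity machinery needs only symmetry and non-negativity.
#'
#' @param values square numeric matrix of distances.
#' @param labels character vector of unique haplotype labels, one per row.
#'   Defaults to `rownames(values)`.
#' @param symmetrize if `TRUE`, small asymmetries (within `tol`) are
#'   averaged away, e.g. after lossy round-trip I/O.  By default exact
#'   symmetry is required.
#' @param tol maximum tolerated asymmetry when `symmetrize = TRUE`.
#' @return a `haplo_dist`: the validated matrix with labels as dimnames.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' haplo_dist(m, labels = c("h1", "h2", "h3"))
#' @export
haplo_dist <- function(values, labels = rownames(values),
                       symmetrize = FALSE, tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("distances must be a numeric matrix", call. = FALSE)
  n <- nrow(values)
  if (ncol(values) != n)
    stop("distance matrix must be square, got ", n, " x ", ncol(values),
         call. = FALSE)
  if (is.null(labels)) labels <- paste0("h", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("need one label per row: ", length(labels), " labels for ",
         n, " rows", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate haplotype labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(labels)))
    stop("haplotype labels must be non-empty strings", call. = FALSE)
  if (any(!is.finite(values)))
    stop("distance matrix contains non-finite entries", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative distance between '", labels[bad[1L]], "' and '",
         labels[bad[2L]], "'", call. = FALSE)
  }
  if (any(diag(values) != 0)) {
    bad <- which(diag(values) != 0)[1L]
    stop("nonzero diagonal entry for '", labels[bad], "'", call. = FALSE)
  }
  asym <- abs(values - t(values))
  if (any(asym > 0)) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    if (!symmetrize || max(asym) > tol)
      stop("asymmetric distances: D('", labels[bad[1L]], "', '",
           labels[bad[2L]], "') = ", values[bad[1L], bad[2L]],
           " but D('", labels[bad[2L]], "', '", labels[bad[1L]], "') = ",
           values[bad[2L], bad[1L]], call. = FALSE)
    values <- (values + t(values)) / 2
  }
  dimnames(values) <- list(labels, labels)
  class(values) <- c("haplo_dist", class(matrix()))
  values
}

#' @export
print.haplo_dist <- function(x, ...) {
  cat("Haplotype distance matrix:", nrow(x), "haplotypes\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname haplo_dist
#' @param x object to coerce/test.
#' @export
as_haplo_dist <- function(x) {
  if (inherits(x, "haplo_dist")) return(x)
  if (inherits(x, "dist")) {
    m <- as.matrix(x)
    return(haplo_dist(m, labels = rownames(m)))
  }
  haplo_dist(as.matrix(x))
}

#' @rdname haplo_dist
#' @export
is_haplo_dist <- function(x) inherits(x, "haplo_dist")

# Resolve a subset of haplotype labels against a distance matrix,
# erroring on unknown labels.  Returns label character vector.
resolve_subset <- function(D, Y = NULL) {
  labels <- rownames(D)
  if (is.null(Y)) return(labels)
  Y <- as.character(Y)
  if (anyDuplicated(Y)) Y <- unique(Y)
  missing <- setdiff(Y, labels)
  if (length(missing))
    stop("unknown haplotype label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  Y
}

#' Hamming distances between aligned haplotype sequences
#'
#' Counts, for every pair of sequences, the number of alignment columns at
#' which they differ.  Gap and ambiguity characters (`-`, `.`, `?`, `N`/`n`
#' by default) are handled by pairwise deletion: a column is skipped for a
#' pair if either sequence carries such a character there.  Set
#' `count_gaps = TRUE` to score those columns like any other (two equal
#' characters match, unequal ones mismatch).
#'
#' @param alignment named character vector of equal-length sequences, or
#'   anything coercible via `as.character` with names (e.g. the result of
#'   [read_fasta()]).
#' @param count_gaps score gap/ambiguity columns instead of excluding them
#'   pairwise.
#' @param ambiguous characters treated as missing data (case-insensitive).
#' @return a [haplo_dist()] of integer-valued Hamming distances.
#' @examples
#' hamming_distances(c(a = "ACGT", b = "ACGA", c = "ACG-"))
#' @export
hamming_distances <- function(alignment, count_gaps = FALSE,
                              ambiguous = c("-", ".", "?", "N")) {
  labels <- names(alignment)
  seqs <- vapply(alignment, function(s) as.character(s)[1L], character(1),
                 USE.NAMES = FALSE)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("alignment sequences must be named by haplotype label",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate haplotype labels in alignment: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  if (lens[1L] < 1L) stop("sequences must have length >= 1", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  amb <- toupper(ambiguous)
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- chars[i, ]
      b <- chars[j, ]
      if (!count_gaps) {
        keep <- !(a %in% amb | b %in% amb)
        a <- a[keep]
        b <- b[keep]
      }
      d <- sum(a != b)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  haplo_dist(D, labels = labels)
}

#' Allele-size distances between microsatellite haplotypes
#'
#' The pairwise haplotypic difference for multilocus microsatellite
#' profiles: the sum over loci of the absolute difference in allele size.
#'
#' @param profiles numeric matrix with one row per haplotype (rownames are
#'   labels) and one column per locus, or a data frame whose first column
#'   is the haplotype label (as written by allele-profile TSV files).
#' @return a [haplo_dist()].
#' @examples
#' p <- rbind(h1 = c(100, 200), h2 = c(102, 199))
#' allele_size_distances(p)  # |2| + |-1| = 3
#' @export
allele_size_distances <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (!is.numeric(profiles[[1L]])) {
      labs <- as.character(profiles[[1L]])
      profiles <- as.matrix(profiles[, -1L, drop = FALSE])
      rownames(profiles) <- labs
    } else {
      profiles <- as.matrix(profiles)
    }
  }
  if (!is.numeric(profiles))
    stop("allele sizes must be numeric", call. = FALSE)
  if (nrow(profiles) < 2L)
    stop("need at least two allele profiles", call. = FALSE)
  if (ncol(profiles) < 1L)
    stop("allele profiles must cover at least one locus", call. = FALSE)
  if (any(!is.finite(profiles)))
    stop("allele profiles contain missing or non-finite sizes (all ",
         "profiles must cover the same loci)", call. = FALSE)
  D <- as.matrix(stats::dist(profiles, method = "manhattan"))
  haplo_dist(D, labels = rownames(profiles))
}
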