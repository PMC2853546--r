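test_that("hamming distances count mismatching alignment columns", {
  D <- hamming_distances(c(a = "ACGT", b = "ACGA"))
  expect_equal(D["a", "b"], 1)
  expect_equal(hamming_distances(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)

  set.seed(11)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:5, function(i)
    paste(sample(bases, 30, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:5)
  D <- hamming_distances(seqs)
  # brute-force position-by-position scan
  for (i in 1:4) for (j in (i + 1):5) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(seqs[j], "")[[1]]
    expect_equal(D[i, j], sum(a != b))
  }
})

test_that("hamming gap handling: pairwise deletion vs counting", {
  al <- c(x = "AC-T", y = "ACGT", z = "ACGA")
  D <- hamming_distances(al)                      # default: exclude pairwise
  expect_equal(D["x", "y"], 0)
  expect_equal(D["x", "z"], 1)
  Dc <- hamming_distances(al, count_gaps = TRUE)  # gap column scored
  expect_equal(Dc["x", "y"], 1)
  expect_equal(Dc["x", "z"], 2)
})

test_that("hamming distances satisfy the triangle inequality", {
  set.seed(12)
  for (rep in 1:10) {
    seqs <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("s", 1:6)
    D <- unclass(hamming_distances(seqs))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("hamming input validation", {
  expect_error(hamming_distances(c(a = "ACG", b = "ACGT")), "aligned")
  expect_error(hamming_distances(setNames(c("AC", "AC"), c("a", "a"))),
               "duplicate")
  expect_error(hamming_distances(c("AC", "AG")), "named")
})

test_that("allele-size distances sum absolute per-locus differences", {
  expect_equal(allele_size_distances(
    rbind(h1 = c(100, 200), h2 = c(102, 199)))["h1", "h2"], 3)
  expect_equal(allele_size_distances(
    rbind(h1 = c(5, 5, 5), h2 = c(5, 5, 5)))["h1", "h2"], 0)

  set.seed(13)
  prof <- matrix(sample(90:110, 6 * 9, replace = TRUE), 6, 9,
                 dimnames = list(paste0("p", 1:6), NULL))
  D <- allele_size_distances(prof)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], sum(abs(prof[i, ] - prof[j, ])))
  # data-frame front-end with an ID column
  df <- data.frame(id = rownames(prof), prof)
  expect_equal(unclass(allele_size_distances(df)), unclass(D))
})

test_that("allele profiles with inconsistent loci are rejected", {
  expect_error(allele_size_distances(rbind(h1 = c(1, NA), h2 = c(1, 2))),
               "loci|finite|missing")
  expect_error(allele_size_distances(matrix(1, 1, 3)), "at least two")
})

test_that("phyletic distances are path lengths along the phylogeny", {
  net <- haplo_net(data.frame(vertex1 = "u", vertex2 = "v"),
                   labels = c(x = "u", y = "v"))
  expect_equal(phyletic_distances(net)["x", "y"], 1)

  set.seed(14)
  for (rep in 1:10) {
    net <- rand_labelled_tree(12, 6)
    D <- phyletic_distances(net)
    edges <- igraph::as_data_frame(net$graph, what = "edges")
    ref <- bfs_distances(edges)     # independent unit-edge BFS
    for (a in names(net$labels)) for (b in names(net$labels))
      expect_equal(D[a, b], ref[net$labels[[a]], net$labels[[b]]])
  }
})

test_that("phyletic tree distances satisfy the four-point condition", {
  set.seed(15)
  for (rep in 1:10) {
    D <- unclass(phyletic_distances(rand_labelled_tree(14, 5)))
    idx <- utils::combn(5, 4)
    for (c0 in seq_len(ncol(idx))) {
      q <- idx[, c0]
      s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                  D[q[1], q[3]] + D[q[2], q[4]],
                  D[q[1], q[4]] + D[q[2], q[3]]))
      expect_equal(s[2], s[3], tolerance = 1e-9)
    }
  }
})

test_that("shortest paths are used on cyclic haplotype networks", {
  # square u-v-w-x-u plus shortcut: distance via shortest route
  net <- haplo_net(data.frame(vertex1 = c("u", "v", "w", "x"),
                              vertex2 = c("v", "w", "x", "u"),
                              length = c(1, 1, 1, 5)),
                   labels = c(a = "u", b = "x"))
  expect_false(net$is_tree)
  expect_equal(phyletic_distances(net)["a", "b"], 3)
})

test_that("distance-matrix validation enforces the invariants", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  D <- haplo_dist(m, labels = c("a", "b", "c"))
  expect_identical(unclass(D)[2, 3], 3)

  bad <- m; bad[1, 2] <- 2
  expect_error(haplo_dist(bad, labels = letters[1:3]), "asymmetric")
  expect_equal(haplo_dist(bad, labels = letters[1:3],
                          symmetrize = TRUE, tol = 2)["a", "b"], 1.5)
  neg <- m; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(haplo_dist(neg, labels = letters[1:3]), "negative")
  dg <- m; dg[2, 2] <- 4
  expect_error(haplo_dist(dg, labels = letters[1:3]), "diagonal")
  nn <- m; nn[1, 3] <- nn[3, 1] <- NaN
  expect_error(haplo_dist(nn, labels = letters[1:3]), "finite")
  expect_error(haplo_dist(m, labels = c("a", "a", "b")), "duplicate")
  # all-identical haplotypes are legitimate
  expect_equal(haplotype_connectivity(haplo_dist(matrix(0, 4, 4))), 0)
})

test_that("all constructors produce valid distance matrices", {
  set.seed(16)
  for (rep in 1:5) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T", "-"), 15, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("s", 1:4)
    prof <- matrix(sample(1:20, 4 * 3, replace = TRUE), 4,
                   dimnames = list(paste0("p", 1:4), NULL))
    for (D in list(hamming_distances(seqs), allele_size_distances(prof),
                   phyletic_distances(rand_labelled_tree(10, 5)))) {
      expect_s3_class(D, "haplo_dist")
      expect_true(all(D >= 0), info = "non-negative")
      expect_equal(unclass(D), t(unclass(D)))
      expect_true(all(diag(D) == 0))
    }
  }
})
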