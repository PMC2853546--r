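test_that("normalize_score maps raw scores onto [0, 1]", {
  expect_equal(normalize_score(14, 3, 25), 0.5)
  expect_equal(round(normalize_score(6, 1, 10), 2), 0.56)
  expect_equal(normalize_score(3, 3, 25), 0)
  expect_equal(normalize_score(25, 3, 25), 1)
  expect_equal(normalize_score(5, 5, 5), 0)       # degenerate range
  expect_error(normalize_score(26, 3, 25), "outside")
  expect_error(normalize_score(2, 3, 25), "outside")
  expect_error(normalize_score(1, 3, 2), "minimum exceeds")
})

test_that("normalize_score is affine-invariant", {
  set.seed(41)
  for (rep in 1:20) {
    lo <- runif(1, 0, 5)
    hi <- lo + runif(1, 0.5, 10)
    raw <- runif(1, lo, hi)
    a <- runif(1, 0.1, 4)
    b <- runif(1, -5, 5)
    expect_equal(normalize_score(a * raw + b, a * lo + b, a * hi + b),
                 normalize_score(raw, lo, hi), tolerance = 1e-10)
  }
})

test_that("region_table validates its input", {
  rt <- region_table(data.frame(haplotype_id = c("a", "b", "a"),
                                region = c("R1", "R1", "R2")))
  expect_equal(rt$R1, c("a", "b"))
  expect_equal(rt$R2, "a")           # haplotypes may occur in many regions
  expect_error(region_table(list(R1 = character(0))), "non-empty")
  expect_error(region_table(list(c("a", "b"))), "name")
})

test_that("a region holding every haplotype gets degenerate-range zeros", {
  set.seed(42)
  net <- rand_labelled_tree(10, 6)
  D <- phyletic_distances(net)
  s <- score_regions(D, list(all = rownames(D)), diversity = "PD",
                     phylogeny = net)
  expect_equal(nrow(s), 1)
  expect_equal(s$div_norm, 0)
  expect_equal(s$hc_norm, 0)
  expect_equal(s$hc_min, s$hc_max)
})

test_that("two distant clusters score higher connectivity than one tight cluster", {
  # region A: 4 haplotypes at mutual distance 1 (tight cluster)
  # region B: two pairs at distance 1 within, 10 between (two clusters)
  labels <- c(paste0("a", 1:4), paste0("b", 1:4))
  m <- matrix(10, 8, 8, dimnames = list(labels, labels))
  m[1:4, 1:4] <- 1
  m[5:6, 5:6] <- 1
  m[7:8, 7:8] <- 1
  diag(m) <- 0
  D <- haplo_dist(m)
  s <- score_regions(D, list(A = paste0("a", 1:4), B = paste0("b", 1:4)),
                     diversity = "AD")
  sA <- s[s$region == "A", ]
  sB <- s[s$region == "B", ]
  expect_gt(sB$hc_norm, sA$hc_norm)
  # brute-force cross-check of the raw and extremal values at k = 4
  expect_equal(sB$hc, 10)
  expect_equal(sA$hc, 1)
  ex <- hc_exhaustive_extrema(D, 4)
  expect_equal(sA$hc_min, unname(ex["min"]))
  expect_equal(sA$hc_max, unname(ex["max"]))
  adex <- ad_exhaustive_extrema(D, 4)
  expect_equal(sA$div_min, unname(adex["min"]))
  expect_equal(sA$div_max, unname(adex["max"]))
})

test_that("score rows respect min <= raw <= max and normalized in [0,1]", {
  set.seed(43)
  for (rep in 1:5) {
    net <- rand_labelled_tree(14, 8)
    D <- phyletic_distances(net)
    labs <- rownames(D)
    regs <- list(r1 = sample(labs, 3), r2 = sample(labs, 5),
                 r3 = sample(labs, 8))
    for (div in c("PD", "AD")) {
      s <- score_regions(D, regs, diversity = div, phylogeny = net)
      expect_true(all(s$div_min <= s$div + 1e-9 & s$div <= s$div_max + 1e-9))
      expect_true(all(s$hc_min <= s$hc & s$hc <= s$hc_max))
      expect_true(all(s$div_norm >= 0 & s$div_norm <= 1))
      expect_true(all(s$hc_norm >= 0 & s$hc_norm <= 1))
      expect_equal(attr(s, "diversity"), div)
    }
  }
})

test_that("scores are invariant to region and haplotype order", {
  set.seed(44)
  net <- rand_labelled_tree(12, 7)
  D <- phyletic_distances(net)
  labs <- rownames(D)
  regs <- list(p = labs[1:4], q = labs[3:7])
  s1 <- score_regions(D, regs, diversity = "PD", phylogeny = net)
  s2 <- score_regions(D, rev(regs), diversity = "PD", phylogeny = net)
  perm <- sample(labs)
  Dp <- haplo_dist(unclass(D)[perm, perm], labels = perm)
  s3 <- score_regions(Dp, lapply(regs, sample), diversity = "PD",
                      phylogeny = net)
  for (s in list(s2, s3)) {
    expect_equal(as.data.frame(s1)[order(s1$region), ],
                 as.data.frame(s)[order(s$region), ],
                 ignore_attr = TRUE)
  }
})

test_that("rows are ordered by normalized diversity, ties by region name", {
  D <- haplo_dist(matrix(c(0, 2, 2, 0), 2, 2), labels = c("x", "y"))
  s <- score_regions(D, list(b = c("x", "y"), a = c("x", "y"), c = "x"),
                     diversity = "AD")
  expect_equal(s$region, c("a", "b", "c"))
})

test_that("configuration errors are reported", {
  D <- rand_dist(5)
  expect_error(score_regions(D, list(r = "h1"), diversity = "PD"),
               "phylogeny")
  expect_error(score_regions(D, list(r = "zz"), diversity = "AD"),
               "unknown")
  cyc <- haplo_net(data.frame(vertex1 = c("u", "v", "w"),
                              vertex2 = c("v", "w", "u")))
  expect_error(score_regions(NULL, list(r = "u"), diversity = "PD",
                             phylogeny = cyc), "tree")
})

test_that("interpretation separates melting-pot-like from hot-spot-like", {
  rows <- data.frame(region = c("m", "h", "l1", "l2"),
                     div_norm = c(0.8, 0.7, 0.1, 0.05),
                     hc_norm = c(0.50, 0.22, 0.9, 0.0))
  ann <- interpret_regions(rows)
  expect_equal(ann$annotation[ann$region == "m"], "melting-pot-like")
  expect_equal(ann$annotation[ann$region == "h"], "hot-spot-like")
  expect_true(all(ann$annotation[ann$region %in% c("l1", "l2")] ==
                  "low-diversity (not assessed)"))
  # all regions identical: same annotation everywhere
  same <- data.frame(region = letters[1:3], div_norm = 0.4, hc_norm = 0.7)
  expect_equal(unique(interpret_regions(same)$annotation),
               "melting-pot-like")
  expect_error(interpret_regions(data.frame()), "region_scores|regions")
})
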