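test_that("downsampling conserves totals and hypergeometric means", {
  counts <- matrix(c(30L, 20L, 10L, 90L, 5L, 5L), nrow = 3,
                   dimnames = list(paste0("f", 1:3), c("a", "b")))
  # identity at the sample's own depth
  same <- downsampleCounts(counts[, 1, drop = FALSE], depth = 60, seed = 1)
  expect_equal(unname(same[, 1]), c(30L, 20L, 10L))
  ds <- downsampleCounts(counts, depth = 50, seed = 2)
  expect_equal(unname(colSums(ds)), c(50L, 50L))
  expect_true(all(ds <= counts))
  # mean over repeated draws matches depth x proportion within 3 SE
  nRep <- 1000
  draws <- numeric(nRep)
  set.seed(3)
  for (i in seq_len(nRep))
    draws[i] <- downsampleCounts(counts[, 1, drop = FALSE], depth = 20)[1, 1]
  N <- 60; K <- 30; n <- 20
  expMean <- n * K / N
  se <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1) / nRep)
  expect_lt(abs(mean(draws) - expMean), 3 * se)
  expect_error(downsampleCounts(counts, depth = 0), "depth")
  expect_warning(downsampleCounts(counts, depth = 70, seed = 4), "dropping")
})

test_that("alpha diversity matches closed forms", {
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_equal(shannonIndex(c(5, 0, 0)), 0)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_equal(richness(c(0.5, 0.25, 0.25)), 3)
  expect_equal(richness(c(1, 0, 2)), 2)
  m <- matrix(c(1, 1, 0, 4), nrow = 2)
  expect_equal(unname(richness(m)), c(2, 1))
  expect_warning(expect_equal(richness(c(0, 0)), 0), "all-zero")
  expect_warning(expect_equal(shannonIndex(c(0, 0)), 0), "all-zero")
})

test_that("taxonomy tree places MGS under their most specific assigned taxon", {
  ann <- data.frame(
    mgs_id = c("M1", "M2"),
    subspecies = NA_character_, species = NA_character_,
    genus = "Bifidobacterium", family = "Bifidobacteriaceae",
    order = "Bifidobacteriales", class = "Actinomycetes",
    phylum = "Actinomycetota", superkingdom = "Bacteria",
    stringsAsFactors = FALSE)
  tr <- taxonomyTree(ann)
  expect_setequal(tr$tip.label, c("M1", "M2"))
  expect_equal(unname(cophenetic(tr)["M1", "M2"]), 2)
  # single MGS
  tr1 <- taxonomyTree(ann[1, ])
  expect_equal(tr1$tip.label, "M1")
  # Newick write/parse round trip preserves the topology and path lengths
  cat1 <- generateCatalog(nMgs = 6, genesPerMgs = 6, signatureSize = 3,
                          seed = 61)
  tr2 <- taxonomyTree(taxonomyTruth(cat1))
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr2, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr2$tip.label)
  expect_equal(cophenetic(back)[tr2$tip.label, tr2$tip.label],
               cophenetic(tr2))
  unlink(f)
  bad <- ann
  bad$family[2] <- "OtherFamily"
  expect_error(taxonomyTree(bad), "non-nested")
})

test_that("weighted UniFrac matches hand and brute-force branch sums", {
  star <- ape::read.tree(text = "(A:1,B:1);")
  ab <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2,
               dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  d <- as.matrix(weightedUnifrac(ab, star))
  expect_equal(d["s1", "s2"], 2)  # disjoint mass: both unit branches differ
  expect_equal(d["s1", "s3"], 0)  # identical samples
  # worked four-leaf tree
  quad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ab4 <- matrix(c(0.5, 0.5, 0, 0,
                  0, 0, 0.5, 0.5,
                  0.25, 0.25, 0.25, 0.25), nrow = 4,
                dimnames = list(c("A", "B", "C", "D"), c("x", "y", "z")))
  d4 <- as.matrix(weightedUnifrac(ab4, quad))
  expect_equal(d4["x", "y"], 4)
  expect_equal(d4["x", "z"], 2)
  # brute-force oracle on random trees and compositions
  set.seed(62)
  for (i in 1:10) {
    tr <- ape::rtree(6)
    a <- runif(6); b <- runif(6)
    names(a) <- names(b) <- tr$tip.label
    m <- cbind(p = a / sum(a), q = b / sum(b))
    got <- as.matrix(weightedUnifrac(m, tr))["p", "q"]
    expect_equal(got, oracleWeightedUnifrac(a, b, tr), tolerance = 1e-12)
  }
  expect_error(weightedUnifrac(ab, ape::read.tree(text = "(A:1,C:1);")),
               "absent from the tree")
})

test_that("weighted UniFrac agrees with an independent implementation", {
  set.seed(63)
  tr <- ape::rtree(8)
  ab <- matrix(runif(8 * 4), nrow = 8,
               dimnames = list(tr$tip.label, paste0("s", 1:4)))
  ab <- sweep(ab, 2, colSums(ab), "/")
  ps <- phyloseq::phyloseq(phyloseq::otu_table(ab, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  for (norm in c(FALSE, TRUE)) {
    ours <- as.matrix(weightedUnifrac(ab, tr, normalized = norm))
    theirs <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                          normalized = norm))
    expect_equal(ours, theirs[rownames(ours), colnames(ours)],
                 tolerance = 1e-10)
  }
})

test_that("UniFrac satisfies the triangle inequality", {
  set.seed(64)
  tr <- ape::rtree(7)
  for (i in 1:50) {
    m <- matrix(runif(21), nrow = 7, dimnames = list(tr$tip.label, 1:3))
    d <- as.matrix(weightedUnifrac(m, tr))
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  x <- c(0, 1, 3, 6)
  d <- dist(x)
  ord <- pcoaOrdination(d)
  got <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(got), unname(as.matrix(d)), tolerance = 1e-9)
  # three mutually equidistant samples: two equal positive eigenvalues
  m3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoaOrdination(m3)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_true(sum(ord3$varianceExplained) <= 1 + 1e-12)
  # degenerate all-zero distances give all-zero coordinates
  z <- matrix(0, 3, 3)
  expect_true(all(abs(pcoaOrdination(z)$coordinates) < 1e-12))
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("PERMANOVA detects separation and respects its conventions", {
  set.seed(65)
  a <- matrix(rnorm(10 * 3), ncol = 3)
  b <- matrix(rnorm(10 * 3, mean = 10), ncol = 3)
  d <- dist(rbind(a, b))
  lab <- rep(c("g1", "g2"), each = 10)
  res <- permanovaTest(d, lab, nPerm = 1000, seed = 66)
  expect_equal(res$p, 1 / 1001)  # minimum attainable with 1000 permutations
  expect_gt(res$R2, 0.9)
  expect_gte(res$p, 1 / (res$nPermutations + 1))
  # identical point sets in both groups carry no group structure
  pts <- matrix(rnorm(8 * 3), ncol = 3)
  d2 <- dist(rbind(pts, pts))
  res2 <- permanovaTest(d2, rep(c("g1", "g2"), each = 8), nPerm = 199,
                        seed = 67)
  expect_lt(res2$R2, 0.05)
  expect_error(permanovaTest(d, rep("g1", 20)), "two groups")
  expect_error(permanovaTest(matrix(0, 4, 4), rep(c("a", "b"), 2)),
               "all-zero")
  # with a single explanatory factor, marginal and sequential SS coincide
  df <- data.frame(g = lab)
  m1 <- vegan::adonis2(d ~ g, data = df, permutations = 99, by = "terms")
  m2 <- vegan::adonis2(d ~ g, data = df, permutations = 99, by = "margin")
  expect_equal(m1$R2[1], m2$R2[1])
  expect_equal(res$R2, m1$R2[1])
})
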