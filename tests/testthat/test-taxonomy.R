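# hand-built hit tables over a toy 10-gene MGS
toyHits <- function(geneIdx, taxon, rank = "species",
                    genus = "Bifidobacterium", identity = 98,
                    alignLen = 150, coverage = 80) {
  base <- data.frame(
    gene_id = paste0("g", geneIdx),
    identity_pct = identity, align_len = alignLen, coverage_pct = coverage,
    subspecies = paste(taxon, "ssp"), species = taxon, genus = genus,
    family = "Bifidobacteriaceae", order = "Bifidobacteriales",
    class = "Actinomycetes", phylum = "Actinomycetota",
    superkingdom = "Bacteria", stringsAsFactors = FALSE)
  if (rank == "genus") {
    base$genus <- taxon
    base$species <- paste(taxon, "sp"); base$subspecies <- paste(taxon, "sp")
  }
  base
}

test_that("hit filtering applies rank-specific identity plus length/coverage", {
  cr <- rankCriteria()
  h <- rbind(toyHits(1, "A", identity = 96, alignLen = 120, coverage = 60),
             toyHits(2, "A", identity = 80, alignLen = 120, coverage = 60),
             toyHits(3, "A", identity = 96, alignLen = 90, coverage = 60),
             toyHits(4, "A", identity = 96, alignLen = 120, coverage = 40))
  sp <- filterHits(h, cr$min_identity[cr$rank == "species"])
  expect_equal(sp$gene_id, "g1")
  gn <- filterHits(h, cr$min_identity[cr$rank == "genus"])  # 85
  expect_equal(gn$gene_id, "g1")
  # identity 80 passes at family (min 75) but length/coverage still gate
  fam <- filterHits(h, 75)
  expect_equal(fam$gene_id, c("g1", "g2"))
  expect_equal(nrow(filterHits(h[0, ], 95)), 0)
})

test_that("rank assignment follows the support and conflict thresholds", {
  genes <- paste0("g", 1:100)
  aAndB <- rbind(toyHits(1:80, "A"), toyHits(96:100, "B"))
  res <- annotateRank(genes, aAndB, "species", 75, 10)
  expect_equal(res$taxon, "A")
  expect_equal(res$support, 80)
  conflicted <- rbind(toyHits(1:80, "A"), toyHits(89:100, "B"))
  expect_true(is.na(annotateRank(genes, conflicted, "species", 75, 10)$taxon))
  expect_true(is.na(annotateRank(genes, aAndB[0, ], "species", 75, 10)$taxon))
  # two taxa at 40% each: neither reaches 75%
  split40 <- rbind(toyHits(1:40, "A"), toyHits(41:80, "B"))
  expect_true(is.na(annotateRank(genes, split40, "species", 75, 10)$taxon))
  # exact support tie with permissive thresholds stays unassigned
  tied <- rbind(toyHits(1:50, "A"), toyHits(51:100, "B"))
  expect_true(is.na(annotateRank(genes, tied, "species", 40, 60)$taxon))
})

test_that("noise-free synthetic hits recover the full eight-rank lineage", {
  cat1 <- generateCatalog(nMgs = 8, genesPerMgs = 12, signatureSize = 10,
                          seed = 41)
  hits <- simulateGeneHits(cat1, seed = 42)
  ann <- annotateMgs(cat1, hits)
  tax <- taxonomyTruth(cat1)
  for (r in c("subspecies", "species", "genus", "family", "order", "class",
              "phylum", "superkingdom"))
    expect_equal(ann[[r]], tax[[r]], info = r)
  expect_true(all(ann$support_species == 100))
})

test_that("species-level support failure falls back to genus with back-fill", {
  cat1 <- generateCatalog(nMgs = 1, genesPerMgs = 20, signatureSize = 10,
                          seed = 43)
  g <- geneInfo(cat1)$gene_id
  lin <- taxonomyTruth(cat1)
  mk <- function(ids, identity) {
    h <- toyHits(1, lin$species[1], identity = identity)
    h <- h[rep(1, length(ids)), ]
    h$gene_id <- ids
    h$subspecies <- lin$subspecies[1]; h$genus <- lin$genus[1]
    h
  }
  # 65% of genes hit at species-grade identity, another 15% only at
  # genus-grade identity: species support 65 < 75, genus support 80 >= 60
  hits <- rbind(mk(g[1:13], 98), mk(g[14:16], 90))
  ann <- annotateMgs(cat1, hits)
  expect_true(is.na(ann$species) || ann$species == lin$species[1])
  expect_equal(ann$genus, lin$genus[1])
  expect_equal(ann$support_genus, 80)
  expect_lt(ann$support_species, 75)
  # parents above genus are back-filled from the genus lineage
  expect_equal(ann$family, lin$family[1])
  expect_equal(ann$superkingdom, "Bacteria")
})

test_that("back-fill restores a parent rank the thresholds rejected", {
  cat1 <- generateCatalog(nMgs = 2, genesPerMgs = 10, signatureSize = 5,
                          seed = 44)
  hits <- simulateGeneHits(cat1, seed = 45)
  cr <- rankCriteria()
  cr$min_support[cr$rank == "genus"] <- 101  # genus can never pass alone
  ann <- annotateMgs(cat1, hits, cr)
  expect_equal(ann$species, taxonomyTruth(cat1)$species)
  expect_equal(ann$genus, taxonomyTruth(cat1)$genus)
})

test_that("raising min_support never gains an assignment", {
  set.seed(46)
  genes <- paste0("g", 1:30)
  for (i in 1:25) {
    n1 <- sample(0:30, 1); n2 <- sample(0:(30 - n1), 1)
    hits <- rbind(
      if (n1) toyHits(sample(30, n1), "A") else NULL,
      if (n2) toyHits(sample(30, n2), "B") else NULL)
    if (is.null(hits) || !nrow(hits)) next
    assignedAt <- vapply(seq(0, 100, by = 10), function(s)
      !is.na(annotateRank(genes, hits, "species", s, 20)$taxon), logical(1))
    # once lost, never regained as support threshold rises
    expect_true(all(diff(as.integer(assignedAt)) <= 0))
  }
})

test_that("annotation is independent of hit ordering", {
  cat1 <- generateCatalog(nMgs = 4, genesPerMgs = 10, signatureSize = 5,
                          seed = 47)
  hits <- simulateGeneHits(cat1, conflictFrac = 0.3, seed = 48)
  set.seed(49)
  ann1 <- annotateMgs(cat1, hits)
  ann2 <- annotateMgs(cat1, hits[sample(nrow(hits)), ])
  expect_equal(ann1, ann2)
})

test_that("a non-nested reference lineage is rejected", {
  h <- rbind(toyHits(1, "A"), toyHits(2, "A"))
  h$family[2] <- "OtherFamily"  # same genus under two families
  cat1 <- generateCatalog(nMgs = 1, genesPerMgs = 2, signatureSize = 1,
                          seed = 50)
  h$gene_id <- geneInfo(cat1)$gene_id
  expect_error(annotateMgs(cat1, h), "conflicting lineage")
})
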