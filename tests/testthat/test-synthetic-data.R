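test_that("catalog generation honours the spec counts and is deterministic", {
  cat1 <- generateCatalog(nMgs = 5, genesPerMgs = 120, signatureSize = 100,
                          seed = 1)
  g <- geneInfo(cat1)
  expect_equal(nrow(g), 600)
  expect_equal(sum(g$is_signature), 500)
  expect_false(anyDuplicated(g$gene_id) > 0)
  sigPerMgs <- tapply(g$is_signature, g$mgs_id, sum)
  expect_true(all(sigPerMgs == 100))
  # signature genes are drawn from each MGS's own genes by construction
  for (m in mgsIds(cat1))
    expect_true(all(signatureGenes(cat1, m) %in% g$gene_id[g$mgs_id == m]))
  # taxonomy: one full eight-rank lineage per MGS
  tax <- taxonomyTruth(cat1)
  expect_equal(nrow(tax), 5)
  expect_false(anyNA(tax[, c("subspecies", "species", "genus", "family",
                             "order", "class", "phylum", "superkingdom")]))
  cat2 <- generateCatalog(nMgs = 5, genesPerMgs = 120, signatureSize = 100,
                          seed = 1)
  expect_identical(geneInfo(cat2), g)
  expect_identical(koTruth(cat2), koTruth(cat1))
  expect_error(generateCatalog(nMgs = 2, genesPerMgs = 8, signatureSize = 10),
               "signatureSize")
})

test_that("KO truth contains positives and negatives for the manual modules", {
  cat1 <- generateCatalog(nMgs = 20, genesPerMgs = 12, signatureSize = 10,
                          seed = 11)
  asg <- assignModules(koTruth(cat1), manualModules())
  expect_true(any(asg))
  expect_false(all(asg))
})

test_that("default cohort design reproduces the published cell counts", {
  des <- cohortDesign()
  expect_equal(unname(des$nPerCell["BM", "Week 1"]), 90)
  expect_equal(unname(des$nPerCell["5HMO", "Week 1"]), 65)
  expect_equal(unname(des$nPerCell["IF", "Week 1"]), 56)
  expect_equal(unname(des$nPerCell["BM", "Month 6"]), 2)
  cat1 <- generateCatalog(nMgs = 5, genesPerMgs = 15, signatureSize = 10,
                          seed = 1)
  truth <- generateCohort(cat1, des, seed = 1)
  cd <- SummarizedExperiment::colData(truth)
  expect_equal(sum(cd$timepoint == "Week 1"), 211)
  expect_equal(ncol(truth), sum(des$nPerCell))
})

test_that("community truths are closed compositions", {
  cat1 <- generateCatalog(nMgs = 8, genesPerMgs = 15, signatureSize = 10,
                          seed = 2)
  truth <- generateCohort(cat1, cohortDesign(timepoints = "W1", nPerCell = 10),
                          seed = 3)
  ab <- SummarizedExperiment::assay(truth, "truth")
  expect_true(all(ab >= 0))
  expect_true(all(abs(colSums(ab) - 1) < 1e-9))
})

test_that("group enrichment raises the targeted taxon and errors on unknowns", {
  cat1 <- generateCatalog(nMgs = 10, genesPerMgs = 15, signatureSize = 10,
                          seed = 4)
  des <- cohortDesign(timepoints = "W1", nPerCell = 100)
  truth <- generateCohort(cat1, des, effectSpec(), seed = 5)
  ab <- SummarizedExperiment::assay(truth, "truth")
  cd <- SummarizedExperiment::colData(truth)
  bif <- taxonomyTruth(cat1)$mgs_id[taxonomyTruth(cat1)$genus == "Bifidobacterium"]
  bifSum <- colSums(ab[bif, , drop = FALSE])
  expect_gt(mean(bifSum[cd$group == "BM"]), mean(bifSum[cd$group == "IF"]))
  # under zero enrichment group labels carry no signal
  truth0 <- generateCohort(cat1, des, effectSpec(enrichment = data.frame(
    group = character(), rank = character(), taxon = character(),
    effect = numeric())), seed = 5)
  ab0 <- SummarizedExperiment::assay(truth0, "truth")
  bif0 <- colSums(ab0[bif, , drop = FALSE])
  expect_lt(abs(mean(bif0[cd$group == "BM"]) - mean(bif0[cd$group == "IF"])),
            0.1)
  expect_error(
    generateCohort(cat1, des, effectSpec(enrichment = data.frame(
      group = "BM", rank = "genus", taxon = "NoSuchGenus", effect = 1))),
    "matches no MGS")
})

test_that("alignment simulation conserves pairs and respects noise fractions", {
  cat1 <- generateCatalog(nMgs = 4, genesPerMgs = 10, signatureSize = 5,
                          seed = 6)
  des <- cohortDesign(timepoints = "W1", nPerCell = 1, depth = 1000)
  truth <- generateCohort(cat1, des, seed = 7)
  noNoise <- effectSpec(multimapFrac = 0, unmappedFrac = 0)
  aln <- simulateAlignments(truth, cat1, noNoise, depth = 1000, seed = 8)[[1]]
  expect_equal(nrow(aln), 2000)  # two mates per pair
  pairs <- classifyPairs(classifyReads(aln), geneToMgs(cat1))
  expect_equal(nrow(pairs), 1000)
  expect_true(all(pairs$category == "MAPPED"))
  expect_error(simulateAlignments(truth, cat1, depth = 0), "depth")
  # determinism
  a2 <- simulateAlignments(truth, cat1, noNoise, depth = 1000, seed = 8)[[1]]
  expect_identical(aln, a2)
})

test_that("a single-MGS community maps only to that MGS's genes", {
  cat1 <- generateCatalog(nMgs = 3, genesPerMgs = 10, signatureSize = 5,
                          seed = 9)
  truth <- generateCohort(cat1, cohortDesign(timepoints = "W1", nPerCell = 1),
                          seed = 10)
  ab <- SummarizedExperiment::assay(truth, "truth")
  ab[, 1] <- c(1, 0, 0)
  SummarizedExperiment::assay(truth, "truth") <- ab
  aln <- simulateAlignments(truth, cat1, effectSpec(multimapFrac = 0,
                                                    unmappedFrac = 0),
                            depth = 500, seed = 11)[[1]]
  genes1 <- geneInfo(cat1)$gene_id[geneInfo(cat1)$mgs_id == mgsIds(cat1)[1]]
  expect_true(all(aln$gene_id %in% genes1))
})

test_that("estimated abundances converge to truth with depth", {
  cat1 <- generateCatalog(nMgs = 5, genesPerMgs = 30, signatureSize = 20,
                          seed = 12)
  truth <- generateCohort(cat1, cohortDesign(timepoints = "W1", nPerCell = 1),
                          seed = 13)
  tv <- SummarizedExperiment::assay(truth, "truth")[, 1]
  maeAt <- function(depth) {
    aln <- simulateAlignments(truth, cat1, depth = depth, seed = 14)
    prof <- profileMgs(buildGeneCounts(aln, cat1)$counts, cat1)
    est <- SummarizedExperiment::assay(prof, "abundance")[, 1]
    mean(abs(est[names(tv)] - tv))
  }
  expect_lt(maeAt(5000), maeAt(500))
})

test_that("simulation files round-trip and are byte-identical under a seed", {
  cat1 <- generateCatalog(nMgs = 3, genesPerMgs = 8, signatureSize = 5,
                          seed = 15)
  truth <- generateCohort(cat1, cohortDesign(timepoints = "W1", nPerCell = 2),
                          seed = 16)
  aln <- simulateAlignments(truth, cat1, depth = 100, seed = 17)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  writeSimulation(d1, cat1, truth, aln)
  writeSimulation(d2, cat1, truth, aln)
  for (f in c("genes.tsv", "taxonomy_truth.tsv", "ko_truth.tsv",
              "catalog.fasta", "samples.tsv", "truth_abundance.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- readAlignmentsTsv(file.path(d1, "alignments",
                                      paste0(names(aln)[1], ".tsv")))
  expect_equal(nrow(back), nrow(aln[[1]]))
  expect_equal(back$gene_id, aln[[1]]$gene_id)
  unlink(c(d1, d2), recursive = TRUE)
})
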