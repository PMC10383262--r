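# Table of per-cell sample counts matching the published three-arm study
# design (fecal samples analysed per feeding group and time point).
.defaultCellCounts <- function() {
  tp <- c("Week 1", "Week 2", "Week 4", "Week 8", "Week 12", "Week 16",
          "Month 6")
  m <- rbind(
    BM     = c(90, 89, 85, 79, 81, 80, 2),
    `5HMO` = c(65, 66, 59, 54, 49, 41, 33),
    IF     = c(56, 46, 41, 30, 26, 23, 15)
  )
  colnames(m) <- tp
  m
}

#' Describe a longitudinal three-group cohort design
#'
#' Defaults emulate the feeding study the package's statistics target:
#' groups BM (breastmilk), 5HMO (formula with a five-HMO mix) and IF
#' (control formula), seven sampling points (Week 1 to Week 16 plus
#' Month 6), and the published per-cell fecal sample counts — including the
#' Month-6 breastmilk cell of only two samples, which exercises the
#' small-sample exclusion rule in the contrast report.
#'
#' @param groups group labels.
#' @param timepoints ordered time point labels.
#' @param nPerCell groups x timepoints matrix of sample counts; recycled
#'   from a single number.
#' @param depth read pairs per sample used when alignments are simulated.
#' @return list of class `cohortDesign`.
#' @export
#' @examples
#' cohortDesign(timepoints = c("Week 1", "Week 2"), nPerCell = 10)
cohortDesign <- function(groups = c("BM", "5HMO", "IF"),
                         timepoints = NULL, nPerCell = NULL,
                         depth = 20000) {
  if (is.null(timepoints) && is.null(nPerCell) &&
      identical(groups, c("BM", "5HMO", "IF"))) {
    nPerCell <- .defaultCellCounts()
    timepoints <- colnames(nPerCell)
  }
  if (is.null(timepoints)) stop("timepoints required", call. = FALSE)
  if (is.null(nPerCell)) nPerCell <- 20
  if (!is.matrix(nPerCell))
    nPerCell <- matrix(nPerCell, nrow = length(groups),
                       ncol = length(timepoints),
                       dimnames = list(groups, timepoints))
  if (any(nPerCell < 0) || any(nPerCell != round(nPerCell)))
    stop("nPerCell must hold non-negative integer counts", call. = FALSE)
  depth <- .assertCount(depth, "depth")
  structure(list(groups = groups, timepoints = timepoints,
                 nPerCell = nPerCell, depth = depth),
            class = "cohortDesign")
}

#' Describe community effect structure for the synthetic cohort
#'
#' Communities follow a compositional log-normal model: each MGS has a
#' baseline log-abundance (drawn once per cohort), per-sample log-normal
#' variation with standard deviation `logSd`, and additive log-scale
#' enrichment effects for chosen (group, taxon) combinations. The default
#' enrichment raises genus *Bifidobacterium* by 2 log-units in the BM and
#' 5HMO groups, the qualitative structure reported for breastfed and
#' HMO-supplemented infants.
#'
#' @param logSd per-sample log-scale dispersion. Default 1.5, giving the
#'   order-of-magnitude spread in Bifidobacterium abundance seen across
#'   real infants.
#' @param enrichment data.frame with columns `group`, `rank`, `taxon`,
#'   `effect` (log-units added to matching MGS in that group).
#' @param multimapFrac,unmappedFrac fractions of simulated read pairs
#'   emitted as multi-mapped / unmapped noise; their sum must be < 1.
#' @return list of class `effectSpec`.
#' @export
#' @examples
#' effectSpec()
effectSpec <- function(logSd = 1.5,
                       enrichment = data.frame(
                         group = c("BM", "5HMO"),
                         rank = "genus",
                         taxon = "Bifidobacterium",
                         effect = 2),
                       multimapFrac = 0.05, unmappedFrac = 0.10) {
  if (logSd <= 0) stop("logSd must be positive", call. = FALSE)
  multimapFrac <- .assertFraction(multimapFrac, "multimapFrac")
  unmappedFrac <- .assertFraction(unmappedFrac, "unmappedFrac")
  if (multimapFrac + unmappedFrac >= 1)
    stop("multimapFrac + unmappedFrac must be < 1", call. = FALSE)
  if (nrow(enrichment) &&
      !all(c("group", "rank", "taxon", "effect") %in% names(enrichment)))
    stop("enrichment needs columns group, rank, taxon, effect", call. = FALSE)
  structure(list(logSd = logSd, enrichment = enrichment,
                 multimapFrac = multimapFrac, unmappedFrac = unmappedFrac),
            class = "effectSpec")
}

# per-group additive log effects resolved to MGS; errors on taxa that match
# nothing in the catalog taxonomy
.effectMatrix <- function(catalog, design, effects) {
  tax <- taxonomyTruth(catalog)
  nMgs <- nrow(tax)
  eff <- matrix(0, nrow = nMgs, ncol = length(design$groups),
                dimnames = list(tax$mgs_id, design$groups))
  enr <- effects$enrichment
  for (i in seq_len(NROW(enr))) {
    rank <- enr$rank[i]
    if (!rank %in% .RANKS)
      stop("unknown rank in enrichment: ", rank, call. = FALSE)
    hit <- tax[[rank]] == enr$taxon[i]
    if (!any(hit))
      stop("enrichment taxon matches no MGS: ", enr$taxon[i], call. = FALSE)
    if (!enr$group[i] %in% design$groups)
      stop("enrichment group not in design: ", enr$group[i], call. = FALSE)
    eff[hit, enr$group[i]] <- eff[hit, enr$group[i]] + enr$effect[i]
  }
  eff
}

#' Generate ground-truth community compositions for a cohort
#'
#' Draws one community per sample from the log-normal model described in
#' [effectSpec()]: per-MGS baseline log-abundances (standard normal, fixed
#' within a cohort), independent normal per-sample deviations of sd
#' `logSd`, plus the group enrichment effects, exponentiated and closed to
#' sum to one.
#'
#' @param catalog an [MgsCatalog-class].
#' @param design a [cohortDesign()].
#' @param effects an [effectSpec()].
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `truth` (MGS x samples relative abundances), `rowData` the taxonomy
#'   truth and `colData` columns `sample_id`, `group`, `timepoint`.
#' @export
#' @examples
#' cat <- generateCatalog(5, 20, 10, seed = 1)
#' des <- cohortDesign(timepoints = "Week 1", nPerCell = 4)
#' truth <- generateCohort(cat, des, seed = 1)
#' colSums(SummarizedExperiment::assay(truth, "truth"))
generateCohort <- function(catalog, design = cohortDesign(),
                           effects = effectSpec(), seed = 1) {
  stopifnot(is(catalog, "MgsCatalog"), inherits(design, "cohortDesign"),
            inherits(effects, "effectSpec"))
  eff <- .effectMatrix(catalog, design, effects)
  tax <- taxonomyTruth(catalog)
  nMgs <- nrow(tax)

  .withSeed(seed, {
    base <- rnorm(nMgs, 0, 1)
    cells <- expand.grid(group = design$groups, timepoint = design$timepoints,
                         stringsAsFactors = FALSE)
    n <- design$nPerCell[cbind(cells$group, cells$timepoint)]
    group <- rep(cells$group, n)
    timepoint <- rep(cells$timepoint, n)
    nSamples <- length(group)
    ab <- matrix(0, nrow = nMgs, ncol = nSamples,
                 dimnames = list(tax$mgs_id, NULL))
    for (j in seq_len(nSamples)) {
      z <- rnorm(nMgs, base, effects$logSd) + eff[, group[j]]
      a <- exp(z)
      ab[, j] <- a / sum(a)
    }
    sampleId <- sprintf("S%04d", seq_len(nSamples))
    colnames(ab) <- sampleId
    SummarizedExperiment::SummarizedExperiment(
      assays = list(truth = ab),
      rowData = tax,
      colData = S4Vectors::DataFrame(sample_id = sampleId, group = group,
                                     timepoint = timepoint,
                                     row.names = sampleId),
      metadata = list(design = design, effects = effects, baseLog = base,
                      seed = seed)
    )
  })
}

# one sample's worth of synthetic alignment records
.simulateSampleAlignments <- function(abund, catalog, effects, depth,
                                      fragmentLength) {
  genes <- geneInfo(catalog)
  effLen <- effectiveLength(genes$length, fragmentLength)
  p <- abund[genes$mgs_id] * effLen
  p <- p / sum(p)

  nMulti <- round(effects$multimapFrac * depth)
  nUnm <- round(effects$unmappedFrac * depth)
  nClean <- depth - nMulti - nUnm

  mkPair <- function(n, gene1, gene2, id1, id2, len1, len2, mq1, mq2,
                     na1, na2, ext1, ext2, provenance) {
    if (n == 0) return(NULL)
    data.frame(
      read_id = rep(sprintf("R%07d", seq_len(n)), each = 2L),
      mate = rep(c(1L, 2L), n),
      gene_id = as.vector(rbind(gene1, gene2)),
      identity_pct = round(as.vector(rbind(id1, id2)), 2),
      align_len = as.vector(rbind(len1, len2)),
      mapq = as.vector(rbind(mq1, mq2)),
      nonaligned_bases = as.vector(rbind(na1, na2)),
      extends_beyond_gene = as.vector(rbind(ext1, ext2)),
      provenance = rep(provenance, each = 2L),
      stringsAsFactors = FALSE
    )
  }

  out <- list()
  if (nClean > 0) {
    g1 <- sample(genes$gene_id, nClean, replace = TRUE, prob = p)
    # mate 2 usually confirms mate 1's gene; sometimes it is multi-mapped or
    # lands on another gene of the same MGS (both still credit mate 1)
    kind <- sample(c("same", "mate2multi", "sameMgs"), nClean, replace = TRUE,
                   prob = c(0.8, 0.1, 0.1))
    g2 <- g1
    sameMgs <- which(kind == "sameMgs")
    if (length(sameMgs)) {
      g2m <- geneToMgs(catalog)[g1[sameMgs]]
      g2[sameMgs] <- vapply(g2m, function(m) {
        cand <- genes$gene_id[genes$mgs_id == m]
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, character(1))
    }
    mq2 <- sample(20:60, nClean, replace = TRUE)
    mq2[kind == "mate2multi"] <- sample(0:19, sum(kind == "mate2multi"),
                                        replace = TRUE)
    out$clean <- mkPair(nClean, g1, g2,
                        runif(nClean, 95, 100), runif(nClean, 95, 100),
                        sample(100:150, nClean, TRUE), sample(100:150, nClean, TRUE),
                        sample(20:60, nClean, TRUE), mq2,
                        sample(0:5, nClean, TRUE), sample(0:5, nClean, TRUE),
                        FALSE, FALSE, "clean")
  }
  if (nMulti > 0) {
    g1 <- sample(genes$gene_id, nMulti, replace = TRUE, prob = p)
    out$multi <- mkPair(nMulti, g1, g1,
                        runif(nMulti, 95, 100), runif(nMulti, 95, 100),
                        sample(100:150, nMulti, TRUE), sample(100:150, nMulti, TRUE),
                        sample(0:19, nMulti, TRUE), sample(0:19, nMulti, TRUE),
                        sample(0:5, nMulti, TRUE), sample(0:5, nMulti, TRUE),
                        FALSE, FALSE, "multimap")
  }
  if (nUnm > 0) {
    g1 <- sample(genes$gene_id, nUnm, replace = TRUE, prob = p)
    # half fail the identity filter, half carry too many nonaligned bases
    ident <- ifelse(runif(nUnm) < 0.5, runif(nUnm, 80, 94.9),
                    runif(nUnm, 95, 100))
    nonal <- ifelse(ident >= 95, sample(11:30, nUnm, TRUE),
                    sample(0:5, nUnm, TRUE))
    out$unmapped <- mkPair(nUnm, g1, g1, ident, ident,
                           sample(100:150, nUnm, TRUE), sample(100:150, nUnm, TRUE),
                           sample(20:60, nUnm, TRUE), sample(20:60, nUnm, TRUE),
                           nonal, nonal, FALSE, FALSE, "unmapped")
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$read_id <- paste0(df$read_id, "_", df$provenance)
  df
}

#' Simulate alignment-record tables for cohort samples
#'
#' For each sample, `depth` read pairs are allocated multinomially to
#' catalog genes with probability proportional to (true MGS abundance x
#' gene effective length); their identities, lengths and mapping qualities
#' are drawn so the pairs pass the uniquely-mapped filters. On top,
#' `multimapFrac` of pairs are emitted below the MAPQ threshold and
#' `unmappedFrac` fail the identity or nonaligned-bases filters. A
#' `provenance` column records each pair's intent (`clean`, `multimap`,
#' `unmapped`); the classifier never reads it, but tests audit
#' classification against it.
#'
#' @param cohort a [generateCohort()] result (or a subset of its columns).
#' @param catalog the [MgsCatalog-class] the cohort was generated from.
#' @param effects the [effectSpec()] holding the noise fractions.
#' @param depth read pairs per sample; default from the cohort's design.
#' @param fragmentLength library fragment length in bp used for the
#'   effective-length weighting (see [effectiveLength()]).
#' @param samples optional character vector restricting which samples to
#'   simulate.
#' @param seed integer seed.
#' @return Named list (one element per sample) of alignment-record
#'   data.frames with columns `read_id`, `mate`, `gene_id`,
#'   `identity_pct`, `align_len`, `mapq`, `nonaligned_bases`,
#'   `extends_beyond_gene`, `provenance`.
#' @export
simulateAlignments <- function(cohort, catalog, effects = effectSpec(),
                               depth = NULL, fragmentLength = 350,
                               samples = NULL, seed = 1) {
  stopifnot(is(cohort, "SummarizedExperiment"), is(catalog, "MgsCatalog"))
  if (is.null(depth)) {
    des <- S4Vectors::metadata(cohort)$design
    depth <- if (!is.null(des)) des$depth else 20000L
  }
  depth <- .assertCount(depth, "depth")
  truth <- SummarizedExperiment::assay(cohort, "truth")
  if (is.null(samples)) samples <- colnames(truth)
  if (!all(samples %in% colnames(truth)))
    stop("unknown sample ids requested", call. = FALSE)
  .withSeed(seed, {
    out <- lapply(samples, function(s)
      .simulateSampleAlignments(truth[, s], catalog, effects, depth,
                                fragmentLength))
    names(out) <- samples
    out
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the catalog FASTA (random sequences of the recorded gene lengths),
#' gene metadata, taxonomy truth, KO truth, sample sheet, truth abundance
#' matrix and one alignment TSV per sample, i.e. everything a pipeline run
#' needs plus the ground truth a validation needs.
#'
#' @param dir output directory (created if missing).
#' @param catalog an [MgsCatalog-class].
#' @param cohort a [generateCohort()] result.
#' @param alignments optional [simulateAlignments()] result; written as
#'   `alignments/<sample>.tsv`.
#' @param fasta logical; write `catalog.fasta` (sequences are generated
#'   from the catalog seed so repeated writes are identical).
#' @return Invisibly, the directory path.
#' @export
writeSimulation <- function(dir, catalog, cohort = NULL, alignments = NULL,
                            fasta = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  genes <- geneInfo(catalog)
  wt(genes, "genes.tsv")
  wt(taxonomyTruth(catalog), "taxonomy_truth.tsv")
  ko <- koTruth(catalog)
  wt(data.frame(mgs_id = rep(names(ko), lengths(ko)),
                ko = unlist(ko, use.names = FALSE)), "ko_truth.tsv")
  if (fasta) {
    seed <- catalog@params$seed
    seqs <- .withSeed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(genes$length, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
    })
    dna <- Biostrings::DNAStringSet(setNames(seqs, genes$gene_id))
    Biostrings::writeXStringSet(dna, file.path(dir, "catalog.fasta"))
  }
  if (!is.null(cohort)) {
    cd <- as.data.frame(SummarizedExperiment::colData(cohort))
    wt(cd, "samples.tsv")
    tr <- SummarizedExperiment::assay(cohort, "truth")
    wt(cbind(data.frame(mgs_id = rownames(tr)), as.data.frame(tr)),
       "truth_abundance.tsv")
  }
  if (!is.null(alignments)) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (s in names(alignments))
      write.table(alignments[[s]], file.path(adir, paste0(s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
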