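# Built-in pool of infant-gut lineages used by the synthetic catalog.
# Covers the taxa the cohort emulation needs: several Bifidobacterium
# species (including the aromatic-lactate-dehydrogenase carriers), the five
# named opportunistic pathogens, and common early-life commensals. For
# species without a named subspecies the subspecies label repeats the
# species name so every MGS carries a complete eight-rank lineage.
.speciesPool <- function() {
  row <- function(phy, cls, ord, fam, gen, sp, ssp = sp)
    data.frame(superkingdom = "Bacteria", phylum = phy, class = cls,
               order = ord, family = fam, genus = gen, species = sp,
               subspecies = ssp, stringsAsFactors = FALSE)
  bif <- function(sp, ssp = sp)
    row("Actinomycetota", "Actinomycetes", "Bifidobacteriales",
        "Bifidobacteriaceae", "Bifidobacterium", sp, ssp)
  rbind(
    bif("Bifidobacterium longum", "Bifidobacterium longum subsp. longum"),
    bif("Bifidobacterium longum", "Bifidobacterium longum subsp. infantis"),
    bif("Bifidobacterium bifidum"),
    bif("Bifidobacterium breve"),
    bif("Bifidobacterium scardovii"),
    bif("Bifidobacterium adolescentis"),
    bif("Bifidobacterium pseudocatenulatum"),
    row("Pseudomonadota", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Escherichia", "Escherichia coli"),
    row("Pseudomonadota", "Gammaproteobacteria", "Enterobacterales",
        "Enterobacteriaceae", "Klebsiella", "Klebsiella pneumoniae"),
    row("Bacillota", "Bacilli", "Lactobacillales", "Enterococcaceae",
        "Enterococcus", "Enterococcus faecalis"),
    row("Bacillota", "Bacilli", "Lactobacillales", "Streptococcaceae",
        "Streptococcus", "Streptococcus agalactiae"),
    row("Bacillota", "Bacilli", "Lactobacillales", "Streptococcaceae",
        "Streptococcus", "Streptococcus salivarius"),
    row("Bacillota", "Clostridia", "Eubacteriales", "Peptostreptococcaceae",
        "Clostridioides", "Clostridioides difficile"),
    row("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
        "Bacteroides", "Bacteroides vulgatus"),
    row("Bacillota", "Negativicutes", "Veillonellales", "Veillonellaceae",
        "Veillonella", "Veillonella parvula"),
    row("Bacillota", "Clostridia", "Eubacteriales", "Lachnospiraceae",
        "Blautia", "Blautia wexlerae"),
    row("Verrucomicrobiota", "Verrucomicrobiae", "Verrucomicrobiales",
        "Akkermansiaceae", "Akkermansia", "Akkermansia muciniphila")
  )
}

# genera a module's KOs are preferentially seeded into, so functional
# contrasts on synthetic cohorts have realistic taxon structure
.modulePreferences <- list(
  fucose_degradation_bifidobacterium = "Bifidobacterium",
  sialic_acid_degradation_ecoli = "Escherichia",
  sialic_acid_degradation_bbreve = "Bifidobacterium",
  mucin_degradation = c("Bifidobacterium", "Akkermansia", "Bacteroides"),
  tyrosine_degradation = c("Bifidobacterium", "Blautia")
)

.assignKoTruth <- function(taxonomy, modules) {
  kos <- vector("list", nrow(taxonomy))
  names(kos) <- taxonomy$mgs_id
  for (i in seq_len(nrow(taxonomy))) {
    genus <- taxonomy$genus[i]
    set <- character()
    for (m in modules) {
      pref <- .modulePreferences[[moduleId(m)]]
      pFull <- if (!is.null(pref) && genus %in% pref) 0.85
               else if (!is.null(pref)) 0.1 else 0.35
      allKos <- unique(unlist(reactionPaths(m)))
      u <- runif(1)
      if (u < pFull) {
        set <- c(set, allKos)
      } else if (u < pFull + 0.3) {
        keep <- runif(length(allKos)) < 0.5
        set <- c(set, allKos[keep])
      }
    }
    # background KOs outside any module keep the sets from being trivially
    # module-shaped
    set <- c(set, sprintf("K9%05d", sample.int(99999L, 5L)))
    kos[[i]] <- sort(unique(set))
  }
  kos
}

#' Generate a synthetic gene catalog with MGS definitions and ground truth
#'
#' Builds a toy analogue of a human-gut gene catalog organised into
#' metagenomic species: `nMgs` MGS each contributing `genesPerMgs` genes, of
#' which `signatureSize` are that MGS's signature genes (100 in the
#' reference workflow). Every MGS receives a full eight-rank lineage drawn
#' from a built-in pool of infant-gut taxa (Bifidobacterium species
#' including the ALDH carriers, the named opportunistic pathogens, common
#' commensals) and a KO set seeded so that the shipped metabolic modules
#' have both complete and partial carriers.
#'
#' @param nMgs number of MGS.
#' @param genesPerMgs genes per MGS (must be >= `signatureSize`).
#' @param signatureSize signature genes per MGS; default 100.
#' @param geneLengthRange two base-pair bounds for uniform gene lengths.
#' @param seed integer seed; the same seed reproduces the catalog exactly.
#' @return An [MgsCatalog-class] object.
#' @export
#' @examples
#' cat <- generateCatalog(nMgs = 5, genesPerMgs = 120, seed = 1)
#' cat
generateCatalog <- function(nMgs, genesPerMgs, signatureSize = 100,
                            geneLengthRange = c(500, 2500), seed = 1) {
  nMgs <- .assertCount(nMgs, "nMgs")
  genesPerMgs <- .assertCount(genesPerMgs, "genesPerMgs")
  signatureSize <- .assertCount(signatureSize, "signatureSize")
  if (signatureSize > genesPerMgs)
    stop("signatureSize must not exceed genesPerMgs", call. = FALSE)
  if (length(geneLengthRange) != 2L || any(geneLengthRange < 1) ||
      geneLengthRange[1] > geneLengthRange[2])
    stop("geneLengthRange must be increasing positive bounds", call. = FALSE)

  .withSeed(seed, {
    mgs_id <- sprintf("MGS%04d", seq_len(nMgs))
    pool <- .speciesPool()
    idx <- rep(seq_len(nrow(pool)), length.out = nMgs)
    taxonomy <- pool[idx, , drop = FALSE]
    rownames(taxonomy) <- NULL
    # recycled pool rows become distinct sister clades of the same species
    dup <- (seq_len(nMgs) - 1L) %/% nrow(pool)
    clade <- dup > 0L
    taxonomy$species[clade] <- paste(taxonomy$species[clade], "clade",
                                     dup[clade] + 1L)
    taxonomy$subspecies[clade] <- paste(taxonomy$subspecies[clade], "clade",
                                        dup[clade] + 1L)
    taxonomy <- cbind(data.frame(mgs_id = mgs_id, stringsAsFactors = FALSE),
                      taxonomy)

    lens <- seq(geneLengthRange[1], geneLengthRange[2])
    genes <- data.frame(
      gene_id = sprintf("G%07d", seq_len(nMgs * genesPerMgs)),
      mgs_id = rep(mgs_id, each = genesPerMgs),
      length = lens[sample.int(length(lens), nMgs * genesPerMgs,
                               replace = TRUE)],
      stringsAsFactors = FALSE
    )
    genes$is_signature <- FALSE
    for (m in mgs_id) {
      rows <- which(genes$mgs_id == m)
      genes$is_signature[sample(rows, signatureSize)] <- TRUE
    }

    modules <- c(manualModules(), gmmModules())
    ko <- .assignKoTruth(taxonomy, modules)

    new("MgsCatalog", genes = genes, taxonomy = taxonomy, ko = ko,
        params = list(nMgs = nMgs, genesPerMgs = genesPerMgs,
                      signatureSize = signatureSize,
                      geneLengthRange = geneLengthRange, seed = seed))
  })
}

#' Simulate per-gene taxonomic hit tables for a catalog
#'
#' Emits one BLAST-style hit per catalog gene against the gene's own truth
#' lineage, at an identity/length/coverage that passes every rank's
#' retention filter. Optionally a fraction of each MGS's genes receive an
#' additional conflicting hit: a different species (and subspecies) of the
#' same genus, which erodes species-level support without touching genus
#' support. Used by annotation round-trip and conflict-suppression tests.
#'
#' @param catalog an [MgsCatalog-class].
#' @param identity,alignLen,coverage hit quality given to the truth hits.
#' @param conflictFrac fraction of each MGS's genes that also hit a
#'   conflicting species of the same genus.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return data.frame with `gene_id`, `identity_pct`, `align_len`,
#'   `coverage_pct` and the eight rank columns of the subject lineage.
#' @export
simulateGeneHits <- function(catalog, identity = 98, alignLen = 150,
                             coverage = 90, conflictFrac = 0, seed = NULL) {
  stopifnot(is(catalog, "MgsCatalog"))
  conflictFrac <- if (conflictFrac == 0) 0 else .assertFraction(conflictFrac, "conflictFrac")
  .withSeed(seed, {
    genes <- geneInfo(catalog)
    tax <- taxonomyTruth(catalog)
    ti <- match(genes$mgs_id, tax$mgs_id)
    hits <- cbind(
      data.frame(gene_id = genes$gene_id, identity_pct = identity,
                 align_len = alignLen, coverage_pct = coverage,
                 stringsAsFactors = FALSE),
      tax[ti, .RANKS, drop = FALSE]
    )
    rownames(hits) <- NULL
    if (conflictFrac > 0) {
      extra <- list()
      for (m in unique(genes$mgs_id)) {
        rows <- which(genes$mgs_id == m)
        n <- ceiling(conflictFrac * length(rows))
        pick <- sample(rows, n)
        lin <- tax[tax$mgs_id == m, , drop = FALSE]
        # a sister species within the same genus; synthesised if the
        # taxonomy holds no other species of that genus
        sisters <- tax[tax$genus == lin$genus & tax$species != lin$species, ,
                       drop = FALSE]
        if (nrow(sisters)) {
          conf <- sisters[1L, , drop = FALSE]
        } else {
          conf <- lin
          conf$species <- paste(lin$species, "conflict")
          conf$subspecies <- paste(lin$subspecies, "conflict")
        }
        block <- cbind(
          data.frame(gene_id = genes$gene_id[pick], identity_pct = identity,
                     align_len = alignLen, coverage_pct = coverage,
                     stringsAsFactors = FALSE),
          conf[rep(1L, n), .RANKS, drop = FALSE]
        )
        extra[[m]] <- block
      }
      hits <- rbind(hits, do.call(rbind, extra))
      rownames(hits) <- NULL
    }
    hits
  })
}
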