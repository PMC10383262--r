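#' Effective gene length
#'
#' Number of valid fragment start positions on a gene: for a library
#' fragment length `fragmentLength` (350 bp by default, the typical
#' sheared-fragment size), a gene of length L offers
#' `max(1, L - fragmentLength + 1)` start positions. The floor of 1 keeps
#' genes shorter than a fragment usable.
#'
#' @param geneLength gene length(s) in bp.
#' @param fragmentLength library fragment length in bp.
#' @return Numeric vector of effective lengths.
#' @export
#' @examples
#' effectiveLength(1000)  # 651
#' effectiveLength(350)   # 1
effectiveLength <- function(geneLength, fragmentLength = 350) {
  if (any(geneLength < 1) || fragmentLength < 1)
    stop("lengths must be >= 1", call. = FALSE)
  pmax(1, geneLength - fragmentLength + 1)
}

#' Sum gene counts over each MGS's signature genes
#'
#' The MGS count is the total of uniquely-mapped-pair counts over that
#' MGS's signature genes only; non-signature genes never contribute.
#' Alongside, the number of signature genes with at least one count is
#' reported, which drives the detection rule.
#'
#' @param geneCounts genes x samples count matrix (all signature genes
#'   must be present as rows).
#' @param catalog an [MgsCatalog-class].
#' @return list with `counts` and `genesHit`, both MGS x samples matrices.
#' @export
countSignature <- function(geneCounts, catalog) {
  stopifnot(is(catalog, "MgsCatalog"))
  genes <- geneInfo(catalog)
  sig <- genes[genes$is_signature, , drop = FALSE]
  miss <- setdiff(sig$gene_id, rownames(geneCounts))
  if (length(miss))
    stop("catalog mismatch: ", length(miss),
         " signature gene(s) missing from the count matrix", call. = FALSE)
  ids <- mgsIds(catalog)
  x <- geneCounts[sig$gene_id, , drop = FALSE]
  grp <- factor(sig$mgs_id, levels = ids)
  counts <- rowsum(x, grp)
  genesHit <- rowsum((x > 0) + 0L, grp)
  list(counts = as.matrix(counts), genesHit = as.matrix(genesHit))
}

#' Estimate per-sample MGS relative abundances
#'
#' An MGS is considered detected in a sample only when reads were uniquely
#' mapped to at least `minSignatureGenes` (default 3) of its signature
#' genes. For detected MGS the abundance score sums, over signature genes,
#' the gene count divided by its effective length (coverage-style
#' normalization); with `pooledLengthNorm = TRUE` the pooled signature
#' count is divided by the mean signature effective length instead. Scores
#' are normalized sample-wise so each sample's detected MGS sum to one;
#' undetected MGS are exactly zero.
#'
#' @param geneCounts genes x samples matrix of uniquely mapped pair counts.
#' @param catalog an [MgsCatalog-class].
#' @param minSignatureGenes detection threshold on distinct signature
#'   genes hit.
#' @param fragmentLength bp, see [effectiveLength()].
#' @param pooledLengthNorm apply length normalization to the pooled MGS
#'   count rather than per gene.
#' @return A [SummarizedExperiment::SummarizedExperiment] (MGS x samples)
#'   with assays `abundance`, `counts`, `genesHit` and `detected`, and the
#'   catalog taxonomy as `rowData` when available.
#' @export
profileMgs <- function(geneCounts, catalog, minSignatureGenes = 3,
                       fragmentLength = 350, pooledLengthNorm = FALSE) {
  minSignatureGenes <- .assertCount(minSignatureGenes, "minSignatureGenes")
  genes <- geneInfo(catalog)
  sig <- genes[genes$is_signature, , drop = FALSE]
  cs <- countSignature(geneCounts, catalog)
  detected <- cs$genesHit >= minSignatureGenes

  ids <- mgsIds(catalog)
  if (pooledLengthNorm) {
    meanEff <- tapply(effectiveLength(sig$length, fragmentLength),
                      factor(sig$mgs_id, levels = ids), mean)
    score <- cs$counts / as.numeric(meanEff)
  } else {
    x <- geneCounts[sig$gene_id, , drop = FALSE] /
      effectiveLength(sig$length, fragmentLength)
    score <- as.matrix(rowsum(x, factor(sig$mgs_id, levels = ids)))
  }
  score[!detected] <- 0
  tot <- colSums(score)
  empty <- tot == 0
  if (any(empty))
    warning(sum(empty), " sample(s) with no detected MGS; ",
            "their abundance rows are all zero")
  tot[empty] <- 1
  abundance <- sweep(score, 2, tot, "/")

  rd <- taxonomyTruth(catalog)
  rd <- if (nrow(rd)) S4Vectors::DataFrame(rd[match(ids, rd$mgs_id), ],
                                           row.names = ids)
        else S4Vectors::DataFrame(row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance, counts = cs$counts,
                  genesHit = cs$genesHit, detected = detected),
    rowData = rd,
    metadata = list(minSignatureGenes = minSignatureGenes,
                    fragmentLength = fragmentLength,
                    pooledLengthNorm = pooledLengthNorm)
  )
}
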