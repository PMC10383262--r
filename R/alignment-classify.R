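#' Classify individual read alignments
#'
#' Applies the unique-mapping filters to each read: a read is UNMAPPED if
#' it has no gene, has more than `maxNonaligned` nonaligned bases, extends
#' beyond the gene boundaries, or fails the identity/length criteria
#' (identity >= 95% over >= 100 aligned bp by default). Reads passing those
#' criteria are UNIQUE when their mapping quality reaches `mapqMin`
#' (default 20) and MULTI otherwise.
#'
#' @param reads data.frame of alignment records with columns `read_id`,
#'   `mate`, `gene_id` (`NA` when the read did not align), `identity_pct`,
#'   `align_len`, `mapq`, `nonaligned_bases`, `extends_beyond_gene`.
#' @param mapqMin,idMin,lenMin,maxNonaligned classification thresholds.
#' @return The input data.frame with an added `status` column
#'   (`"UNIQUE"`, `"MULTI"` or `"UNMAPPED"`).
#' @export
#' @examples
#' rec <- data.frame(read_id = "r1", mate = 1, gene_id = "g1",
#'                   identity_pct = 96, align_len = 120, mapq = 30,
#'                   nonaligned_bases = 2, extends_beyond_gene = FALSE)
#' classifyReads(rec)$status
classifyReads <- function(reads, mapqMin = 20, idMin = 95, lenMin = 100,
                          maxNonaligned = 10) {
  need <- c("read_id", "mate", "gene_id", "identity_pct", "align_len",
            "mapq", "nonaligned_bases", "extends_beyond_gene")
  if (!all(need %in% names(reads)))
    stop("alignment records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(mapqMin < 0, idMin <= 0, lenMin <= 0, maxNonaligned < 0))
    stop("thresholds must be positive", call. = FALSE)
  hasGene <- !is.na(reads$gene_id) & nzchar(as.character(reads$gene_id))
  num <- cbind(reads$identity_pct, reads$align_len, reads$mapq,
               reads$nonaligned_bases)
  if (any(hasGene & (is.na(num[, 1]) | apply(num, 1, function(r) any(r < 0, na.rm = TRUE)))))
    stop("malformed alignment record: negative or missing fields", call. = FALSE)

  unmapped <- !hasGene |
    reads$nonaligned_bases > maxNonaligned |
    reads$extends_beyond_gene |
    reads$identity_pct < idMin |
    reads$align_len < lenMin
  unmapped[is.na(unmapped)] <- TRUE
  status <- ifelse(unmapped, "UNMAPPED",
                   ifelse(reads$mapq >= mapqMin, "UNIQUE", "MULTI"))
  reads$status <- status
  reads
}

#' Classify read pairs from per-read statuses
#'
#' Pairs are classified as: UNMAPPED when both reads are unmapped; MULTI
#' when both are multi-mapped or one is multi-mapped and the other
#' unmapped; MAPPED when at least one read is uniquely mapped and the pair
#' can be credited to a single gene (both unique to the same gene, one
#' unique with an unmapped/multi-mapped mate, or the two reads unique to
#' different genes of the same MGS, credited to the mate-1 gene). Pairs
#' whose two reads map uniquely to genes of *different* MGS fall outside
#' those categories and are flagged DISCORDANT; they are excluded from
#' gene counts.
#'
#' @param reads a data.frame as returned by [classifyReads()] (two rows per
#'   `read_id`, mates 1 and 2).
#' @param geneToMgs named character vector mapping gene ids to MGS ids
#'   (see [geneToMgs()]).
#' @param onUnpaired `"error"` (default) or `"drop"` for read ids that do
#'   not have exactly one mate 1 and one mate 2.
#' @return data.frame with one row per pair: `read_id`, `category`
#'   (`MAPPED`, `MULTI`, `UNMAPPED`, `DISCORDANT`) and `gene_id` (the
#'   credited gene for MAPPED pairs, otherwise `NA`).
#' @export
classifyPairs <- function(reads, geneToMgs, onUnpaired = c("error", "drop")) {
  onUnpaired <- match.arg(onUnpaired)
  if (!"status" %in% names(reads))
    stop("run classifyReads() first (missing 'status' column)", call. = FALSE)
  m1 <- reads[reads$mate == 1L, , drop = FALSE]
  m2 <- reads[reads$mate == 2L, , drop = FALSE]
  ok1 <- !duplicated(m1$read_id)
  ok2 <- !duplicated(m2$read_id)
  ids <- intersect(m1$read_id, m2$read_id)
  bad <- unique(c(m1$read_id[!ok1], m2$read_id[!ok2],
                  setdiff(c(m1$read_id, m2$read_id), ids)))
  if (length(bad)) {
    if (onUnpaired == "error")
      stop(length(bad), " read id(s) without exactly two mates; ",
           "set onUnpaired = 'drop' to discard them", call. = FALSE)
    warning("dropping ", length(bad), " read id(s) without exactly two mates")
    ids <- setdiff(ids, bad)
  }
  i1 <- match(ids, m1$read_id)
  i2 <- match(ids, m2$read_id)
  s1 <- m1$status[i1]; s2 <- m2$status[i2]
  g1 <- as.character(m1$gene_id[i1]); g2 <- as.character(m2$gene_id[i2])

  mapped1 <- s1 == "UNIQUE"; mapped2 <- s2 == "UNIQUE"
  category <- rep(NA_character_, length(ids))
  credit <- rep(NA_character_, length(ids))

  bothUnm <- s1 == "UNMAPPED" & s2 == "UNMAPPED"
  category[bothUnm] <- "UNMAPPED"
  multi <- !bothUnm & !mapped1 & !mapped2
  category[multi] <- "MULTI"

  one <- xor(mapped1, mapped2)
  category[one] <- "MAPPED"
  credit[one] <- ifelse(mapped1[one], g1[one], g2[one])

  both <- mapped1 & mapped2
  if (any(both)) {
    miss <- setdiff(unique(c(g1[both], g2[both])), names(geneToMgs))
    if (length(miss))
      stop("genes missing from the gene-to-MGS lookup: ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    sameGene <- both & g1 == g2
    category[sameGene] <- "MAPPED"; credit[sameGene] <- g1[sameGene]
    diffGene <- both & g1 != g2
    sameMgs <- diffGene & geneToMgs[g1] == geneToMgs[g2]
    # same-MGS pairs credit the mate-1 gene; MGS-level sums are unaffected
    category[sameMgs] <- "MAPPED"; credit[sameMgs] <- g1[sameMgs]
    category[diffGene & !sameMgs] <- "DISCORDANT"
  }
  data.frame(read_id = ids, category = category, gene_id = credit,
             stringsAsFactors = FALSE)
}

#' Build the per-sample gene count matrix of uniquely mapped read pairs
#'
#' Runs read- and pair-level classification on each sample's alignment
#' records and counts one per MAPPED pair on its credited gene.
#' Multi-mapped, unmapped and discordant pairs contribute nothing, and the
#' four category counts always sum to the number of input pairs.
#'
#' @param alignments a single alignment-record data.frame or a named list
#'   of them (one element per sample).
#' @param catalog an [MgsCatalog-class] (or a named gene-to-MGS character
#'   vector).
#' @param mapqMin,idMin,lenMin,maxNonaligned read-level thresholds, see
#'   [classifyReads()].
#' @param onUnpaired see [classifyPairs()].
#' @return list with `counts` (genes x samples integer matrix over all
#'   catalog genes) and `summary` (per-sample data.frame of pair-category
#'   counts).
#' @export
buildGeneCounts <- function(alignments, catalog, mapqMin = 20, idMin = 95,
                            lenMin = 100, maxNonaligned = 10,
                            onUnpaired = c("error", "drop")) {
  onUnpaired <- match.arg(onUnpaired)
  if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
  lut <- if (is(catalog, "MgsCatalog")) geneToMgs(catalog) else catalog
  genes <- names(lut)
  counts <- matrix(0L, nrow = length(genes), ncol = length(alignments),
                   dimnames = list(genes, names(alignments)))
  summary <- data.frame(sample = names(alignments), pairs = 0L, MAPPED = 0L,
                        MULTI = 0L, UNMAPPED = 0L, DISCORDANT = 0L,
                        stringsAsFactors = FALSE)
  for (j in seq_along(alignments)) {
    pairs <- classifyPairs(
      classifyReads(alignments[[j]], mapqMin, idMin, lenMin, maxNonaligned),
      lut, onUnpaired = onUnpaired)
    tab <- table(factor(pairs$category,
                        levels = c("MAPPED", "MULTI", "UNMAPPED", "DISCORDANT")))
    summary[j, c("MAPPED", "MULTI", "UNMAPPED", "DISCORDANT")] <- as.integer(tab)
    summary$pairs[j] <- nrow(pairs)
    hit <- pairs$gene_id[pairs$category == "MAPPED"]
    bad <- setdiff(unique(hit), genes)
    if (length(bad))
      stop("credited genes absent from the catalog: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    t2 <- table(factor(hit, levels = genes))
    counts[, j] <- as.integer(t2)
  }
  list(counts = counts, summary = summary)
}

#' Write a gene count matrix as genes x samples TSV
#'
#' @param counts genes x samples matrix (e.g. `buildGeneCounts()$counts`).
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeGeneCounts <- function(counts, file) {
  write.table(cbind(data.frame(gene_id = rownames(counts)),
                    as.data.frame(counts)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
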