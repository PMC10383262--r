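#' Per-rank annotation criteria
#'
#' The tiered criteria used to aggregate per-gene hits into an MGS-level
#' taxon call. At each rank a taxon is assigned when at least
#' `min_support` percent of the MGS's genes have a retained hit to it and
#' no more than `max_conflict` percent have a retained hit to any other
#' taxon at that rank; hits are retained at a rank only when alignment
#' length >= 100 bp, query coverage >= 50% and identity reaches the rank's
#' `min_identity`.
#'
#' @return data.frame with columns `rank`, `min_support`, `max_conflict`,
#'   `min_identity`, ordered from subspecies to superkingdom.
#' @export
#' @examples
#' rankCriteria()
rankCriteria <- function() {
  data.frame(
    rank = .RANKS,
    min_support = c(75, 75, 60, 50, 40, 30, 25, 20),
    max_conflict = c(10, 10, 10, 20, 20, 20, 20, 15),
    min_identity = c(95, 95, 85, 75, 65, 55, 50, 45),
    stringsAsFactors = FALSE
  )
}

#' Filter gene hits for one rank
#'
#' @param hits data.frame of gene hits with `identity_pct`, `align_len`,
#'   `coverage_pct` and the eight rank columns.
#' @param minIdentity rank-specific identity threshold (percent).
#' @param minLen minimum alignment length in bp.
#' @param minCoverage minimum query coverage (percent).
#' @return The retained subset of `hits`.
#' @export
filterHits <- function(hits, minIdentity, minLen = 100, minCoverage = 50) {
  keep <- hits$align_len >= minLen & hits$coverage_pct >= minCoverage &
    hits$identity_pct >= minIdentity
  hits[keep, , drop = FALSE]
}

#' Annotate one MGS at one rank
#'
#' Support for a candidate taxon is the fraction of the MGS's genes (the
#' full catalog membership, not only genes with hits) having at least one
#' retained hit to that taxon; conflict is the fraction with a retained
#' hit to any other taxon at the rank. The taxon is assigned when support
#' reaches `minSupport` and conflict stays within `maxConflict` (both
#' percent). If
#' several taxa qualify the best-supported one wins; an exact support tie
#' leaves the rank unassigned.
#'
#' @param memberGenes character vector of all the MGS's gene ids.
#' @param hits retained hits (already filtered, restricted to this MGS's
#'   genes) with a column named after `rank`.
#' @param rank one of the eight rank names.
#' @param minSupport,maxConflict percent thresholds.
#' @return list with `taxon` (or `NA`) and `support` (percent).
#' @export
annotateRank <- function(memberGenes, hits, rank, minSupport, maxConflict) {
  n <- length(memberGenes)
  if (!n) stop("MGS has no member genes", call. = FALSE)
  if (!nrow(hits)) return(list(taxon = NA_character_, support = 0))
  taxa <- unique(hits[[rank]])
  support <- vapply(taxa, function(t)
    100 * length(unique(hits$gene_id[hits[[rank]] == t])) / n, numeric(1))
  conflict <- vapply(taxa, function(t)
    100 * length(unique(hits$gene_id[hits[[rank]] != t])) / n, numeric(1))
  ok <- support >= minSupport & conflict <= maxConflict
  if (!any(ok)) {
    return(list(taxon = NA_character_, support = unname(max(support))))
  }
  cand <- which(ok)
  best <- cand[support[cand] == max(support[cand])]
  if (length(best) > 1L)
    return(list(taxon = NA_character_, support = unname(support[best[1]])))
  list(taxon = unname(taxa[best]), support = unname(support[best]))
}

# reference lineage table from hit rows; errors if a taxon at some rank
# maps to more than one parent (non-nested reference taxonomy)
.referenceLineage <- function(hits) {
  lin <- unique(hits[, .RANKS, drop = FALSE])
  for (i in seq_len(length(.RANKS) - 1L)) {
    child <- .RANKS[i]; parent <- .RANKS[i + 1L]
    map <- unique(lin[, c(child, parent)])
    if (anyDuplicated(map[[child]]))
      stop("conflicting lineage in reference taxonomy at rank ", child,
           call. = FALSE)
  }
  lin
}

#' Annotate MGS with eight-rank taxonomy from gene hit tables
#'
#' Evaluates every rank independently under [rankCriteria()] (rank-specific
#' hit filtering, support and conflict thresholds), then enforces lineage
#' consistency: whenever a rank is assigned, all its parent ranks are
#' back-filled from that taxon's reference lineage, overwriting an absent
#' or conflicting parent call so downstream rank-level grouping always
#' sees nested labels.
#'
#' @param catalog an [MgsCatalog-class] giving MGS gene membership.
#' @param hits data.frame of gene hits (`gene_id`, `identity_pct`,
#'   `align_len`, `coverage_pct` plus the eight rank columns of each
#'   subject's lineage).
#' @param criteria a [rankCriteria()]-shaped data.frame.
#' @return data.frame with one row per MGS: `mgs_id`, the eight rank
#'   columns (NA where unassigned) and `support_<rank>` percent columns.
#' @export
annotateMgs <- function(catalog, hits, criteria = rankCriteria()) {
  stopifnot(is(catalog, "MgsCatalog"))
  if (!all(.RANKS %in% criteria$rank))
    stop("criteria must cover all eight ranks", call. = FALSE)
  genes <- geneInfo(catalog)
  lineage <- if (nrow(hits)) .referenceLineage(hits) else NULL
  hitMgs <- genes$mgs_id[match(hits$gene_id, genes$gene_id)]

  out <- lapply(mgsIds(catalog), function(m) {
    member <- genes$gene_id[genes$mgs_id == m]
    mh <- hits[!is.na(hitMgs) & hitMgs == m, , drop = FALSE]
    assigned <- setNames(rep(NA_character_, 8L), .RANKS)
    support <- setNames(numeric(8L), .RANKS)
    for (i in seq_along(.RANKS)) {
      cr <- criteria[criteria$rank == .RANKS[i], ]
      fh <- filterHits(mh, cr$min_identity)
      res <- annotateRank(member, fh, .RANKS[i], cr$min_support,
                          cr$max_conflict)
      assigned[i] <- res$taxon
      support[i] <- res$support
    }
    # lineage-consistency pass, child wins upward
    for (i in seq_len(length(.RANKS) - 1L)) {
      if (is.na(assigned[i])) next
      row <- lineage[lineage[[.RANKS[i]]] == assigned[i], , drop = FALSE][1L, ]
      for (j in (i + 1L):length(.RANKS)) {
        parentVal <- row[[.RANKS[j]]]
        if (is.na(assigned[j]) || assigned[j] != parentVal)
          assigned[j] <- parentVal
      }
      break
    }
    c(list(mgs_id = m), as.list(assigned),
      as.list(setNames(support, paste0("support_", .RANKS))))
  })
  do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
}
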