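#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic counts pairs where an `x`
#' value exceeds a `y` value, with half-credit for ties. The p-value is
#' exact (full enumeration) when the pooled sample size is at most 12 and
#' the data are tie-free; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `U` and `p`.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  if (all(pooled == pooled[1]))  # degenerate: no rank information at all
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(U = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Cliff's delta effect size
#'
#' The probability that a value from `x` exceeds one from `y` minus the
#' probability of the reverse: `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`,
#' in \[-1, 1\], positive when `x` tends to be larger.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' cliffsDelta(c(1, 2, 3), c(4, 5, 6))  # -1
cliffsDelta <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  mean(sign(outer(x, y, "-")))
}

#' Benjamini-Hochberg adjustment with discovery flags
#'
#' Standard step-up adjustment within one multiple-testing family; a test
#' is a discovery when its adjusted value is at or below the target false
#' discovery rate (10% in the reference analysis).
#'
#' @param p vector of p-values in \[0, 1\] (NAs pass through).
#' @param fdr target FDR.
#' @return list with `q` (adjusted values) and `discovery` (logical).
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))$q  # all 0.04
bhAdjust <- function(p, fdr = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- p.adjust(p, method = "BH")
  list(q = q, discovery = !is.na(q) & q <= fdr)
}

#' Pairwise group contrasts per feature and time point
#'
#' For every feature, time point and unordered group pair, computes group
#' medians, the Mann-Whitney U statistic and two-sided p-value, and
#' Cliff's delta (positive when the first group of the pair is higher).
#' BH adjustment is applied within families defined by `familyBy`
#' (default: each time point is one family, pooling all features and
#' group pairs, matching a per-time-point presentation). Cells where
#' either group has fewer than `minN` samples are reported but not tested
#' (`tested = FALSE`, NA statistics) — e.g. a two-sample Month-6 cell —
#' and features that are all zero within a time point are likewise
#' skipped.
#'
#' @param features features x samples matrix (or SummarizedExperiment).
#' @param sampleSheet data.frame with `sample_id`, `group`, `timepoint`.
#' @param minN minimum per-group sample size for testing.
#' @param fdr target false discovery rate for the discovery flag.
#' @param familyBy columns of the result defining one BH family.
#' @return data.frame with one row per (feature, timepoint, pair):
#'   `feature`, `timepoint`, `group1`, `group2`, `n1`, `n2`, `median1`,
#'   `median2`, `U`, `p`, `cliffs_delta`, `q`, `significant`, `tested`.
#' @export
contrastTable <- function(features, sampleSheet, minN = 3, fdr = 0.10,
                          familyBy = "timepoint") {
  mat <- .asFeatureMatrix(features)
  need <- c("sample_id", "group", "timepoint")
  if (!all(need %in% names(sampleSheet)))
    stop("sampleSheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(colnames(mat) %in% sampleSheet$sample_id))
    stop("unknown samples in the feature matrix", call. = FALSE)
  ss <- sampleSheet[match(colnames(mat), sampleSheet$sample_id), ]
  groups <- unique(ss$group)
  if (length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2L)

  rows <- list()
  for (tp in unique(ss$timepoint)) {
    inTp <- ss$timepoint == tp
    for (k in seq_len(ncol(pairs))) {
      gA <- pairs[1, k]; gB <- pairs[2, k]
      selA <- inTp & ss$group == gA
      selB <- inTp & ss$group == gB
      nA <- sum(selA); nB <- sum(selB)
      for (f in rownames(mat)) {
        xa <- mat[f, selA]; xb <- mat[f, selB]
        testable <- nA >= minN && nB >= minN && any(c(xa, xb) != 0)
        if (testable) {
          mw <- mannWhitneyU(xa, xb)
          rows[[length(rows) + 1L]] <- data.frame(
            feature = f, timepoint = tp, group1 = gA, group2 = gB,
            n1 = nA, n2 = nB,
            median1 = median(xa), median2 = median(xb),
            U = mw$U, p = mw$p, cliffs_delta = cliffsDelta(xa, xb),
            tested = TRUE, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            feature = f, timepoint = tp, group1 = gA, group2 = gB,
            n1 = nA, n2 = nB,
            median1 = if (nA) median(xa) else NA_real_,
            median2 = if (nB) median(xb) else NA_real_,
            U = NA_real_, p = NA_real_, cliffs_delta = NA_real_,
            tested = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  fam <- interaction(out[, familyBy, drop = FALSE], drop = TRUE)
  for (lev in levels(fam)) {
    sel <- fam == lev & out$tested
    if (any(sel)) out$q[sel] <- bhAdjust(out$p[sel], fdr)$q
  }
  out$significant <- !is.na(out$q) & out$q <= fdr
  rownames(out) <- NULL
  out
}

#' Effect-size table for heat-map style reporting
#'
#' One row per (feature, timepoint, pair) with the signed Cliff's delta
#' (positive = first group higher), significance stars binned on the raw
#' p-value (`*` < 0.05, `**` < 0.01, `***` < 0.001) and the FDR discovery
#' flag carried separately. Untested small-sample cells keep their row
#' with missing effect size.
#'
#' @param contrasts a [contrastTable()] result.
#' @return data.frame with `feature`, `timepoint`, `pair`, `cliffs_delta`,
#'   `p`, `stars`, `q_significant`.
#' @export
heatmapExport <- function(contrasts) {
  stars <- rep("", nrow(contrasts))
  p <- contrasts$p
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  data.frame(
    feature = contrasts$feature,
    timepoint = contrasts$timepoint,
    pair = paste(contrasts$group1, "vs", contrasts$group2),
    cliffs_delta = contrasts$cliffs_delta,
    p = contrasts$p,
    stars = stars,
    q_significant = contrasts$significant,
    stringsAsFactors = FALSE
  )
}

#' Aggregate MGS abundances to a taxonomic rank
#'
#' Sums relative abundances over MGS sharing the same label at `rank`;
#' unannotated MGS are pooled under `"unassigned"`.
#'
#' @param abundance MGS x samples matrix or SummarizedExperiment.
#' @param annotation data.frame with `mgs_id` and rank columns.
#' @param rank target rank.
#' @return taxa x samples matrix.
#' @export
aggregateByRank <- function(abundance, annotation, rank = "genus") {
  ab <- .asFeatureMatrix(abundance)
  lab <- annotation[[rank]][match(rownames(ab), annotation$mgs_id)]
  lab[is.na(lab)] <- "unassigned"
  as.matrix(rowsum(ab, lab))
}

#' PCoA coordinates with group centroids
#'
#' Convenience export of ordination coordinates joined with sample
#' metadata, plus per-group-by-timepoint centroids of the first two axes.
#'
#' @param ordination a [pcoaOrdination()] result.
#' @param sampleSheet data.frame with `sample_id`, `group`, `timepoint`.
#' @return list with `samples` and `centroids` data.frames.
#' @export
pcoaExport <- function(ordination, sampleSheet) {
  co <- ordination$coordinates
  df <- data.frame(sample_id = rownames(co),
                   Axis1 = co[, 1],
                   Axis2 = if (ncol(co) > 1) co[, 2] else 0,
                   stringsAsFactors = FALSE)
  df <- merge(df, sampleSheet, by = "sample_id", sort = FALSE)
  cen <- aggregate(cbind(Axis1, Axis2) ~ group + timepoint, df, mean)
  list(samples = df, centroids = cen)
}

#' Per-group mean abundance of the top taxa
#'
#' Mean relative abundance per group and time point for the `k` taxa with
#' the highest overall mean, the shape behind stacked-composition
#' overviews.
#'
#' @param rankAbundance taxa x samples matrix ([aggregateByRank()]).
#' @param sampleSheet data.frame with `sample_id`, `group`, `timepoint`.
#' @param k number of top taxa to keep.
#' @return data.frame with `taxon`, `group`, `timepoint`, `mean_abundance`.
#' @export
topTaxaSummary <- function(rankAbundance, sampleSheet, k = 20) {
  keep <- names(sort(rowMeans(rankAbundance), decreasing = TRUE))
  keep <- head(keep, k)
  ss <- sampleSheet[match(colnames(rankAbundance), sampleSheet$sample_id), ]
  out <- list()
  for (t in keep) {
    agg <- aggregate(list(mean_abundance = rankAbundance[t, ]),
                     by = list(group = ss$group, timepoint = ss$timepoint),
                     FUN = mean)
    agg$taxon <- t
    out[[t]] <- agg
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("taxon", "group", "timepoint", "mean_abundance")]
}
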