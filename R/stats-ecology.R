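#' Downsample a count matrix without replacement
#'
#' Random subsampling of read counts without replacement (rarefaction) so
#' every retained sample sums to the same depth; per-feature counts then
#' follow the multivariate hypergeometric distribution. Samples whose
#' total is below the depth are dropped with a warning (or kept untouched
#' with `drop = FALSE`).
#'
#' @param counts features x samples non-negative integer matrix.
#' @param depth target total per sample; default the smallest sample
#'   total.
#' @param seed integer seed, or `NULL`.
#' @param drop drop samples with fewer than `depth` counts.
#' @return Downsampled features x samples matrix.
#' @export
downsampleCounts <- function(counts, depth = NULL, seed = NULL, drop = TRUE) {
  tot <- colSums(counts)
  if (is.null(depth)) depth <- min(tot)
  depth <- .assertCount(depth, "depth")
  low <- tot < depth
  if (any(low)) {
    if (drop) {
      warning("dropping ", sum(low), " sample(s) below depth ", depth)
      counts <- counts[, !low, drop = FALSE]
    } else {
      stop("samples below the requested depth; use drop = TRUE", call. = FALSE)
    }
  }
  .withSeed(seed, {
    # vegan advises against rarefying matrices that look like proportions;
    # integer counts are part of this function's contract, so mute that
    out <- withCallingHandlers(
      t(vegan::rrarefy(t(counts), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  storage.mode(out) <- "integer"
  out
}

#' Alpha diversity: richness and Shannon index
#'
#' Richness is the number of features with a positive count; the Shannon
#' index is computed in natural log units on the relative proportions.
#' All-zero samples get richness 0 and Shannon 0 with a warning.
#'
#' @param x non-negative vector, or a features x samples matrix (one value
#'   per sample/column).
#' @return `richness()` integer count(s); `shannonIndex()` numeric nats.
#' @export
#' @examples
#' shannonIndex(rep(1, 4))  # log(4)
richness <- function(x) {
  if (is.matrix(x)) return(apply(x, 2L, richness))
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(x) == 0) warning("all-zero sample: richness 0")
  sum(x > 0)
}

#' @rdname richness
#' @export
shannonIndex <- function(x) {
  if (is.matrix(x)) return(apply(x, 2L, shannonIndex))
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(x) == 0) {
    warning("all-zero sample: Shannon 0")
    return(0)
  }
  unname(vegan::diversity(x, index = "shannon", base = exp(1)))
}

#' Build a rank-layered taxonomy tree for UniFrac
#'
#' With no phylogeny stated for the profiled MGS, beta diversity uses a
#' tree derived from the taxonomic annotation: internal nodes are the
#' assigned taxa from superkingdom down to the most specific assigned
#' rank, every edge has unit length, and MGS are the leaves attached under
#' their most specific assigned taxon. Chains of single-child nodes are
#' collapsed (path lengths are preserved), and a non-nested lineage table
#' is an error.
#'
#' @param annotation data.frame with `mgs_id` and the eight rank columns
#'   ([annotateMgs()] output or taxonomy truth).
#' @return An [ape::phylo] rooted tree with MGS ids as tip labels.
#' @export
taxonomyTree <- function(annotation) {
  stopifnot(all(c("mgs_id", .RANKS) %in% names(annotation)))
  ranks <- rev(.RANKS)  # superkingdom first
  lin <- annotation[, c("mgs_id", ranks)]
  # nestedness check on assigned ranks
  for (i in seq_len(length(ranks) - 1L)) {
    sub <- lin[!is.na(lin[[ranks[i + 1L]]]) & !is.na(lin[[ranks[i]]]),
               c(ranks[i + 1L], ranks[i])]
    map <- unique(sub)
    if (anyDuplicated(map[[1L]]))
      stop("non-nested lineage at rank ", ranks[i + 1L], call. = FALSE)
  }
  esc <- function(x) gsub("[ ():,;]", "_", x)
  build <- function(rows, depth) {
    if (depth > length(ranks)) {
      return(paste0(esc(rows$mgs_id), ":1", collapse = ","))
    }
    lab <- rows[[ranks[depth]]]
    leaves <- rows[is.na(lab), , drop = FALSE]
    parts <- character()
    if (nrow(leaves))
      parts <- c(parts, paste0(esc(leaves$mgs_id), ":1"))
    for (t in unique(lab[!is.na(lab)])) {
      sub <- rows[!is.na(lab) & lab == t, , drop = FALSE]
      inner <- build(sub, depth + 1L)
      # single leaf below: attach directly (collapse the chain)
      parts <- c(parts, paste0("(", inner, ")", esc(t), ":1"))
    }
    paste(parts, collapse = ",")
  }
  nwk <- paste0("(", build(lin, 1L), ")root;")
  tree <- ape::read.tree(text = nwk)
  if (length(tree$tip.label) > 1L) tree <- ape::collapse.singles(tree)
  # restore the original ids (escaping only touched punctuation)
  tree$tip.label <- annotation$mgs_id[match(tree$tip.label,
                                            esc(annotation$mgs_id))]
  tree
}

#' Weighted UniFrac distances
#'
#' For samples A and B with relative abundances spread over the tips of a
#' rooted tree, the (raw) weighted UniFrac distance sums, over branches,
#' the branch length times the absolute difference in the abundance
#' fraction descending through that branch. With `normalized = TRUE` the
#' raw distance is divided by the abundance-weighted total branch depth,
#' scaling it into \[0, 1\].
#'
#' @param abundance features x samples matrix (or SummarizedExperiment);
#'   columns are renormalized to proportions.
#' @param tree rooted [ape::phylo] whose tips cover all features.
#' @param normalized divide by the weighted maximal distance.
#' @return A [stats::dist] object over samples.
#' @export
weightedUnifrac <- function(abundance, tree, normalized = FALSE) {
  ab <- .asFeatureMatrix(abundance)
  miss <- setdiff(rownames(ab), tree$tip.label)
  if (length(miss))
    stop("features absent from the tree: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  tot <- colSums(ab)
  tot[tot == 0] <- 1
  ab <- sweep(ab, 2, tot, "/")

  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  # per-node mass for every sample by postorder accumulation
  mass <- matrix(0, nrow = nNode, ncol = ncol(ab))
  idx <- match(tree$tip.label, rownames(ab))
  present <- !is.na(idx)
  mass[which(present), ] <- ab[idx[present], , drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  len <- po$edge.length
  for (k in seq_len(nrow(edge)))
    mass[edge[k, 1], ] <- mass[edge[k, 1], ] + mass[edge[k, 2], ]
  branchMass <- mass[edge[, 2], , drop = FALSE]

  weighted <- branchMass * len
  d <- stats::dist(t(weighted), method = "manhattan")
  if (normalized) {
    depth <- colSums(branchMass * len)
    ij <- which(lower.tri(matrix(0, ncol(ab), ncol(ab))), arr.ind = TRUE)
    denom <- depth[ij[, 2]] + depth[ij[, 1]]
    denom[denom == 0] <- 1
    d <- d / denom
  }
  attr(d, "Labels") <- colnames(ab)
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix via eigendecomposition of
#' the double-centered Gram matrix. Negative eigenvalues are reported but
#' excluded from the variance-explained fractions.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending) and `varianceExplained` (fractions over the positive
#'   eigenvalues).
#' @export
pcoaOrdination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  k <- max(1L, n - 1L)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  eig <- fit$eig
  ord <- order(eig, decreasing = TRUE)
  eig <- eig[ord]
  pos <- eig[eig > 1e-12]
  ve <- if (length(pos)) pos / sum(pos) else numeric()
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0)
    coords <- matrix(0, nrow = n, ncol = 1,
                     dimnames = list(rownames(m), "Axis1"))
  else
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig, varianceExplained = ve)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance partitioning the
#' squared-distance variance by a single grouping factor. The test
#' statistic is the pseudo-F with (k - 1, n - k) degrees of freedom; the
#' p-value counts permuted statistics at least as extreme as the observed
#' one, including the observed labelling, over free label permutations.
#' Computation delegates to `vegan::adonis2`; with a single explanatory
#' factor the sequential and marginal sums of squares coincide, so the
#' `by` setting is immaterial.
#'
#' @param d distance matrix or [stats::dist].
#' @param labels grouping factor (at least two groups).
#' @param nPerm number of permutations (1000 by default).
#' @param seed integer seed for the permutation stream.
#' @return list with `R2`, `F`, `p`, `nPermutations` and `table` (the
#'   underlying anova table).
#' @export
permanovaTest <- function(d, labels, nPerm = 1000, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("PERMANOVA needs at least two groups", call. = FALSE)
  m <- as.matrix(d)
  if (all(m == 0)) stop("all-zero distances: pseudo-F undefined", call. = FALSE)
  if (length(labels) != nrow(m))
    stop("labels must match the distance matrix", call. = FALSE)
  nPerm <- .assertCount(nPerm, "nPerm")
  df <- data.frame(group = labels)
  fit <- .withSeed(seed, {
    vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                   permutations = nPerm, by = "terms")
  })
  list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1],
       nPermutations = nPerm, table = fit)
}
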