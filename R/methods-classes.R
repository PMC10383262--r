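#' Accessors for MgsCatalog objects
#'
#' `geneInfo()` returns the gene table (gene_id, mgs_id, length,
#' is_signature); `mgsIds()` the MGS identifiers; `taxonomyTruth()` the
#' eight-rank lineage table; `koTruth()` the per-MGS KO sets;
#' `signatureGenes(x, mgs)` the signature gene ids of one MGS;
#' `geneToMgs()` a named character vector mapping gene ids to MGS ids.
#'
#' @param x an [MgsCatalog-class] object.
#' @param mgs single MGS identifier.
#' @return See the individual accessor descriptions.
#' @name MgsCatalog-accessors
#' @examples
#' cat <- generateCatalog(nMgs = 3, genesPerMgs = 12, signatureSize = 10, seed = 1)
#' head(geneInfo(cat))
#' mgsIds(cat)
#' signatureGenes(cat, mgsIds(cat)[1])
NULL

#' @rdname MgsCatalog-accessors
#' @export
setMethod("geneInfo", "MgsCatalog", function(x) x@genes)

#' @rdname MgsCatalog-accessors
#' @export
setMethod("mgsIds", "MgsCatalog", function(x) unique(x@genes$mgs_id))

#' @rdname MgsCatalog-accessors
#' @export
setMethod("taxonomyTruth", "MgsCatalog", function(x) x@taxonomy)

#' @rdname MgsCatalog-accessors
#' @export
setMethod("koTruth", "MgsCatalog", function(x) x@ko)

#' @rdname MgsCatalog-accessors
#' @export
setMethod("signatureGenes", "MgsCatalog", function(x, mgs) {
  g <- x@genes
  g$gene_id[g$mgs_id == mgs & g$is_signature]
})

#' @rdname MgsCatalog-accessors
#' @export
setMethod("geneToMgs", "MgsCatalog", function(x) {
  setNames(x@genes$mgs_id, x@genes$gene_id)
})

setMethod("show", "MgsCatalog", function(object) {
  g <- object@genes
  cat("MgsCatalog with", length(unique(g$mgs_id)), "MGS,",
      nrow(g), "genes (", sum(g$is_signature), "signature )\n")
  if (nrow(object@taxonomy)) {
    gen <- unique(object@taxonomy$genus)
    cat("  genera:", paste(head(gen, 6), collapse = ", "),
        if (length(gen) > 6) "..." else "", "\n")
  }
  if (length(object@ko))
    cat("  KO truth for", length(object@ko), "MGS\n")
})

#' Accessors for GutModule objects
#'
#' @param x a [GutModule-class] object.
#' @return `moduleId()`/`moduleName()` a string; `reactionPaths()` the list
#'   of paths (each a list of KO-alternative character vectors).
#' @name GutModule-accessors
#' @examples
#' m <- manualModules()[[1]]
#' moduleId(m)
#' reactionPaths(m)
NULL

#' @rdname GutModule-accessors
#' @export
setMethod("moduleId", "GutModule", function(x) x@moduleId)

#' @rdname GutModule-accessors
#' @export
setMethod("moduleName", "GutModule", function(x) x@name)

#' @rdname GutModule-accessors
#' @export
setMethod("reactionPaths", "GutModule", function(x) x@paths)

setMethod("show", "GutModule", function(object) {
  ns <- vapply(object@paths, length, integer(1))
  thr <- if (object@thresholdRule == "fixed")
    sprintf("fixed %.2f", object@thresholdValue) else "auto"
  cat(sprintf("GutModule %s (%s): %d path(s) of %s step(s), threshold %s\n",
              object@moduleId, object@name, length(object@paths),
              paste(ns, collapse = "/"), thr))
})
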