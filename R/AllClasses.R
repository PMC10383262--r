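#' MgsCatalog: a gene catalog with MGS definitions and ground truth
#'
#' Container for a (possibly synthetic) gene catalog organised into
#' metagenomic species (MGS). Each gene belongs to exactly one MGS; a fixed
#' subset of each MGS's genes (100 in the reference workflow) are its
#' signature genes, whose uniquely-mapped read-pair counts quantify the MGS.
#' The catalog optionally carries per-MGS taxonomic lineages (eight ranks)
#' and per-MGS KEGG Orthology (KO) sets, which the synthetic generator fills
#' in as ground truth for recovery tests.
#'
#' @slot genes data.frame with columns `gene_id`, `mgs_id`, `length`
#'   (bp) and `is_signature` (logical).
#' @slot taxonomy data.frame with `mgs_id` plus the eight rank columns
#'   `subspecies`, `species`, `genus`, `family`, `order`, `class`,
#'   `phylum`, `superkingdom`.
#' @slot ko named list mapping `mgs_id` to a character vector of KO ids.
#' @slot params list of the generator parameters used to build the catalog
#'   (empty for catalogs loaded from files).
#'
#' @aliases MgsCatalog-class
#' @exportClass MgsCatalog
setClass("MgsCatalog",
  representation(
    genes = "data.frame",
    taxonomy = "data.frame",
    ko = "list",
    params = "list"
  )
)

setValidity("MgsCatalog", function(object) {
  g <- object@genes
  msg <- character()
  need <- c("gene_id", "mgs_id", "length", "is_signature")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msg <- c(msg, "gene identifiers must be unique across the catalog")
  if (any(g$length <= 0))
    msg <- c(msg, "gene lengths must be positive")
  if (nrow(object@taxonomy)) {
    if (!all(c("mgs_id", .RANKS) %in% names(object@taxonomy)))
      msg <- c(msg, "taxonomy must have mgs_id plus the eight rank columns")
    else if (!all(unique(g$mgs_id) %in% object@taxonomy$mgs_id))
      msg <- c(msg, "every MGS must have a taxonomy row")
  }
  if (length(msg)) msg else TRUE
})

#' GutModule: a metabolic module as alternative reaction paths of KO steps
#'
#' A Gut Metabolic Module (GMM) is a curated metabolic pathway expressed as
#' one or more alternative reaction paths; each path is an ordered series of
#' enzymatic steps, and each step is satisfied by any one of a set of
#' alternative KO identifiers. A module is assigned to an MGS when the
#' best-covered path reaches the module's completeness threshold: all steps
#' for modules whose shortest path has fewer than four steps, two-thirds of
#' the steps otherwise, or a fixed fraction (three-fifths for the manually
#' curated fucose/sialic-acid modules).
#'
#' @slot moduleId single character module identifier.
#' @slot name human-readable module name.
#' @slot paths list of reaction paths; each path is a list of steps; each
#'   step is a non-empty character vector of alternative KO ids.
#' @slot thresholdRule `"auto"` (all-steps / two-thirds rule) or `"fixed"`.
#' @slot thresholdValue completeness fraction used when
#'   `thresholdRule == "fixed"`; `NA` otherwise.
#'
#' @aliases GutModule-class
#' @exportClass GutModule
setClass("GutModule",
  representation(
    moduleId = "character",
    name = "character",
    paths = "list",
    thresholdRule = "character",
    thresholdValue = "numeric"
  )
)

setValidity("GutModule", function(object) {
  msg <- character()
  if (length(object@moduleId) != 1L || !nzchar(object@moduleId))
    msg <- c(msg, "moduleId must be a single non-empty string")
  if (!length(object@paths))
    msg <- c(msg, "a module needs at least one reaction path")
  for (p in object@paths) {
    if (!length(p) || !all(vapply(p, function(s) is.character(s) && length(s) > 0 && all(nzchar(s)), logical(1)))) {
      msg <- c(msg, "every path must be a list of non-empty KO alternative sets")
      break
    }
  }
  if (!object@thresholdRule %in% c("auto", "fixed"))
    msg <- c(msg, "thresholdRule must be 'auto' or 'fixed'")
  if (object@thresholdRule == "fixed" &&
      (is.na(object@thresholdValue) || object@thresholdValue <= 0 || object@thresholdValue > 1))
    msg <- c(msg, "fixed thresholdValue must be in (0, 1]")
  if (length(msg)) msg else TRUE
})
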