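#' @rdname MgsCatalog-accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname MgsCatalog-accessors
#' @export
setGeneric("mgsIds", function(x) standardGeneric("mgsIds"))

#' @rdname MgsCatalog-accessors
#' @export
setGeneric("taxonomyTruth", function(x) standardGeneric("taxonomyTruth"))

#' @rdname MgsCatalog-accessors
#' @export
setGeneric("koTruth", function(x) standardGeneric("koTruth"))

#' @rdname MgsCatalog-accessors
#' @export
setGeneric("signatureGenes", function(x, mgs) standardGeneric("signatureGenes"))

#' @rdname MgsCatalog-accessors
#' @export
setGeneric("geneToMgs", function(x) standardGeneric("geneToMgs"))

#' @rdname GutModule-accessors
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' @rdname GutModule-accessors
#' @export
setGeneric("moduleName", function(x) standardGeneric("moduleName"))

#' @rdname GutModule-accessors
#' @export
setGeneric("reactionPaths", function(x) standardGeneric("reactionPaths"))
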