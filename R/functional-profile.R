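#' Construct a GutModule
#'
#' @param moduleId module identifier.
#' @param name human-readable name.
#' @param paths list of reaction paths, each a list of character vectors of
#'   alternative KO ids (a plain character vector is taken as a single
#'   path of single-KO steps).
#' @param threshold `"auto"` for the all-steps / two-thirds rule, or a
#'   fixed completeness fraction in (0, 1].
#' @return A [GutModule-class] object.
#' @export
#' @examples
#' gutModule("M1", "toy", c("K00001", "K00002", "K00003"))
gutModule <- function(moduleId, name, paths, threshold = "auto") {
  if (is.character(paths)) paths <- list(as.list(paths))
  if (is.list(paths) && length(paths) && !is.list(paths[[1]]))
    paths <- list(lapply(paths, as.character))
  paths <- lapply(paths, function(p) lapply(p, as.character))
  if (identical(threshold, "auto")) {
    rule <- "auto"; val <- NA_real_
  } else {
    rule <- "fixed"; val <- as.numeric(threshold)
  }
  new("GutModule", moduleId = moduleId, name = name, paths = paths,
      thresholdRule = rule, thresholdValue = val)
}

#' Manually curated HMO-related degradation modules
#'
#' Three modules annotated from species-specific pathways rather than the
#' module catalog: Bifidobacterium-specific fucose degradation
#' (K02431, K07046, K18334, K22397, K02429), sialic-acid degradation after
#' the Escherichia coli pathway (K01639, K00885, K01877, K01443, K02564)
#' and after the Bifidobacterium breve pathway (K01714, K02564, K25026,
#' K01788, K01443). Each is a single five-KO path assigned when at least
#' three-fifths of its KOs are present.
#'
#' @return Named list of three [GutModule-class] objects.
#' @export
manualModules <- function() {
  mk <- function(id, name, kos)
    gutModule(id, name, as.character(kos), threshold = 3 / 5)
  list(
    fucose_degradation_bifidobacterium = mk(
      "fucose_degradation_bifidobacterium",
      "Bifidobacterium-specific fucose degradation",
      c("K02431", "K07046", "K18334", "K22397", "K02429")),
    sialic_acid_degradation_ecoli = mk(
      "sialic_acid_degradation_ecoli",
      "sialic acid degradation (Escherichia coli pathway)",
      c("K01639", "K00885", "K01877", "K01443", "K02564")),
    sialic_acid_degradation_bbreve = mk(
      "sialic_acid_degradation_bbreve",
      "sialic acid degradation (Bifidobacterium breve pathway)",
      c("K01714", "K02564", "K25026", "K01788", "K01443"))
  )
}

#' Read Gut Metabolic Module definitions from a structured text file
#'
#' Format: a module starts with `MODULE <id> <name>`, followed by one line
#' per step listing its alternative KO ids separated by spaces or commas.
#' A line `//` separates alternative reaction paths within a module and
#' `///` ends the module. Lines starting with `#` are comments.
#'
#' @param file path; defaults to the curated module subset shipped with
#'   the package (a small stand-in for the full 103-module catalog —
#'   supply your own file to use the complete set).
#' @return Named list of [GutModule-class] objects.
#' @export
gmmModules <- function(file = system.file("extdata", "gmm_modules.txt",
                                          package = "mgskit")) {
  lines <- trimws(readLines(file))
  lines <- lines[!startsWith(lines, "#")]
  modules <- list()
  id <- NULL; name <- NULL; paths <- list(); steps <- list()
  flushPath <- function() {
    if (length(steps)) paths[[length(paths) + 1L]] <<- steps
    steps <<- list()
  }
  flushModule <- function() {
    flushPath()
    if (!is.null(id)) {
      modules[[id]] <<- gutModule(id, name, paths)
    }
    id <<- NULL; name <<- NULL; paths <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (startsWith(ln, "MODULE")) {
      flushModule()
      parts <- strsplit(sub("^MODULE\\s+", "", ln), "\\s+")[[1]]
      id <- parts[1]
      name <- paste(parts[-1], collapse = " ")
      if (!nzchar(name)) name <- id
    } else if (ln == "///") {
      flushModule()
    } else if (ln == "//") {
      flushPath()
    } else {
      kos <- strsplit(ln, "[, \t]+")[[1]]
      steps[[length(steps) + 1L]] <- kos[nzchar(kos)]
    }
  }
  flushModule()
  modules
}

#' Fraction of a reaction path's steps covered by a KO set
#'
#' A step is covered when at least one of its alternative KOs is present.
#'
#' @param kos character vector of KO ids carried by an MGS.
#' @param path list of steps (character vectors of KO alternatives).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' pathCoverage(c("K1", "K2"), list("K1", "K2", "K3"))  # 2/3
pathCoverage <- function(kos, path) {
  if (!length(path)) stop("path must be non-empty", call. = FALSE)
  mean(vapply(path, function(step) any(step %in% kos), logical(1)))
}

#' Decide whether a module is assigned to a KO set
#'
#' The completeness threshold is: all steps when the module's shortest
#' path has fewer than four steps; two-thirds of the steps of any reaction
#' path otherwise; or the module's fixed fraction (three-fifths for the
#' manual modules). The module is assigned when the best-covered path
#' reaches the threshold.
#'
#' @param kos character vector of KO ids carried by an MGS.
#' @param module a [GutModule-class].
#' @return Logical.
#' @export
#' @examples
#' assignModule(c("K02431", "K07046", "K18334"), manualModules()[[1]])
assignModule <- function(kos, module) {
  stopifnot(is(module, "GutModule"))
  paths <- reactionPaths(module)
  thr <- if (module@thresholdRule == "fixed") {
    module@thresholdValue
  } else if (min(vapply(paths, length, integer(1))) < 4L) {
    1
  } else {
    2 / 3
  }
  cov <- vapply(paths, function(p) pathCoverage(kos, p), numeric(1))
  any(cov >= thr - 1e-9)
}

#' Assign a set of modules across all MGS of a catalog or KO table
#'
#' @param ko named list of KO sets per MGS (e.g. [koTruth()]).
#' @param modules list of [GutModule-class] objects.
#' @return Logical MGS x modules matrix.
#' @export
assignModules <- function(ko, modules) {
  ids <- vapply(modules, moduleId, character(1))
  m <- vapply(modules, function(mod)
    vapply(ko, assignModule, logical(1), module = mod),
    logical(length(ko)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ko))
  dimnames(m) <- list(names(ko), ids)
  m
}

#' Summed relative abundance of module-carrying MGS
#'
#' For each sample and module, the relative abundances of the MGS assigned
#' that module are summed, giving the community fraction with the
#' functional potential the module describes.
#'
#' @param assignments logical MGS x modules matrix ([assignModules()]).
#' @param abundance MGS x samples relative-abundance matrix or a
#'   [profileMgs()]/[generateCohort()] SummarizedExperiment.
#' @return Modules x samples numeric matrix with values in \[0, 1\].
#' @export
moduleAbundance <- function(assignments, abundance) {
  ab <- .asFeatureMatrix(abundance)
  common <- intersect(rownames(assignments), rownames(ab))
  if (!length(common))
    stop("no shared MGS ids between assignments and abundances", call. = FALSE)
  t(assignments[common, , drop = FALSE]) %*% ab[common, , drop = FALSE]
}

#' Default taxon lists for functional species groups
#'
#' `aldhSpecies()` returns the Bifidobacterium taxa carrying an aromatic
#' lactate dehydrogenase (able to produce aromatic lactic acids);
#' `pathogenSpecies()` the default opportunistic-pathogen list (the five
#' named species; extend it with the full predefined 33-species list via
#' the `extra` argument of [groupAbundance()] configs).
#'
#' @return Character vector of taxon labels.
#' @export
aldhSpecies <- function() {
  c("Bifidobacterium longum subsp. longum",
    "Bifidobacterium longum subsp. infantis",
    "Bifidobacterium bifidum",
    "Bifidobacterium breve",
    "Bifidobacterium scardovii")
}

#' @rdname aldhSpecies
#' @export
pathogenSpecies <- function() {
  c("Escherichia coli", "Enterococcus faecalis", "Clostridioides difficile",
    "Klebsiella pneumoniae", "Streptococcus agalactiae")
}

#' Summed abundance of a configurable species group
#'
#' Sums, per sample, the relative abundances of MGS whose annotation at
#' `rank` (or at subspecies, which is also checked so subspecies-level
#' labels like the ALDH carriers match) is in `taxa`.
#'
#' @param abundance MGS x samples matrix or SummarizedExperiment.
#' @param annotation data.frame with `mgs_id` and rank columns
#'   ([annotateMgs()] output or a taxonomy truth table).
#' @param taxa character vector of taxon labels.
#' @param rank rank at which the labels are stated; default `"species"`.
#' @return Named numeric vector (one value per sample).
#' @export
groupAbundance <- function(abundance, annotation, taxa, rank = "species") {
  ab <- .asFeatureMatrix(abundance)
  idx <- match(rownames(ab), annotation$mgs_id)
  lab <- annotation[[rank]][idx]
  hit <- !is.na(lab) & lab %in% taxa
  if ("subspecies" %in% names(annotation) && rank != "subspecies") {
    ssp <- annotation$subspecies[idx]
    hit <- hit | (!is.na(ssp) & ssp %in% taxa)
  }
  if (!any(hit)) {
    warning("no MGS matched the taxon list; returning zeros")
    return(setNames(numeric(ncol(ab)), colnames(ab)))
  }
  colSums(ab[hit, , drop = FALSE])
}

#' Split Bifidobacterium abundance by aromatic lactic acid potential
#'
#' Within genus Bifidobacterium, ALDH+ MGS are those whose species or
#' subspecies annotation is in `aldhTaxa`; ALDH- is the bifidobacterial
#' remainder, so the two rows always sum to the genus total.
#'
#' @param abundance MGS x samples matrix or SummarizedExperiment.
#' @param annotation taxonomy table with `mgs_id`, `genus`, `species`,
#'   `subspecies`.
#' @param aldhTaxa taxon labels of the ALDH carriers.
#' @return 2 x samples matrix with rows `ALDHpos` and `ALDHneg`.
#' @export
aldhPartition <- function(abundance, annotation, aldhTaxa = aldhSpecies()) {
  ab <- .asFeatureMatrix(abundance)
  idx <- match(rownames(ab), annotation$mgs_id)
  isBif <- !is.na(annotation$genus[idx]) & annotation$genus[idx] == "Bifidobacterium"
  lab <- annotation$species[idx]
  ssp <- if ("subspecies" %in% names(annotation)) annotation$subspecies[idx] else lab
  isAldh <- isBif & ((!is.na(lab) & lab %in% aldhTaxa) |
                     (!is.na(ssp) & ssp %in% aldhTaxa))
  rbind(
    ALDHpos = colSums(ab[isAldh, , drop = FALSE]),
    ALDHneg = colSums(ab[isBif & !isAldh, , drop = FALSE])
  )
}
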