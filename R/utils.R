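# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; with seed = NULL the current stream is used.
.withSeed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x >= 1)
    stop(sprintf("'%s' must be a proportion in [0, 1)", name), call. = FALSE)
  as.numeric(x)
}

# canonical rank order, most specific first
.RANKS <- c("subspecies", "species", "genus", "family", "order", "class",
            "phylum", "superkingdom")

# coerce an abundance-like input (matrix or SummarizedExperiment with an
# "abundance" or first assay) to a features x samples numeric matrix
.asFeatureMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if ("abundance" %in% nm) "abundance" else 1L
    x <- SummarizedExperiment::assay(x, a)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) stop("feature matrix must have rownames", call. = FALSE)
  storage.mode(x) <- "double"
  x
}
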