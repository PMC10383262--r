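# CIGAR helpers: query/reference span in bases for the given operation set
.cigarOpSum <- function(cigar, ops) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    tot <- 0L
    for (k in seq_along(starts)) {
      piece <- substr(cg, starts[k], starts[k] + lens[k] - 1L)
      op <- substr(piece, nchar(piece), nchar(piece))
      if (op %in% ops)
        tot <- tot + as.integer(substr(piece, 1L, nchar(piece) - 1L))
    }
    tot
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignment records from the TSV dialect
#'
#' The TSV dialect carries the classifier's fields directly: `read_id`,
#' `mate`, `gene_id` (empty or NA for unaligned reads), `identity_pct`,
#' `align_len`, `mapq`, `nonaligned_bases`, `extends_beyond_gene`, plus an
#' optional `provenance` column written by the simulator and ignored by
#' the pipeline.
#'
#' @param file path to a tab-separated alignment table.
#' @return data.frame of alignment records.
#' @export
readAlignmentsTsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("read_id", "mate", "gene_id", "identity_pct", "align_len",
            "mapq", "nonaligned_bases", "extends_beyond_gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("alignment TSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$gene_id[!is.na(df$gene_id) & df$gene_id == ""] <- NA_character_
  df$extends_beyond_gene <- as.logical(df$extends_beyond_gene)
  df
}

#' Read alignment records from a SAM file
#'
#' Converts a SAM file into the package's alignment-record table. Identity
#' is derived from the NM tag as `100 * (1 - NM / aligned_length)`, the
#' aligned length from the CIGAR M/=/X operations, nonaligned bases from
#' soft clips plus insertions, and the beyond-gene flag from the alignment
#' end position against the gene length in the header. Mates are taken from
#' the first/last-segment flag bits.
#'
#' @param file path to a SAM file with `@SQ` header lines and NM tags.
#' @return data.frame of alignment records as in [readAlignmentsTsv()].
#' @export
readAlignmentsSam <- function(file) {
  bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets

  flag <- x$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  gene <- as.character(x$rname)
  gene[unmapped] <- NA_character_
  alen <- .cigarOpSum(x$cigar, c("M", "=", "X"))
  refSpan <- .cigarOpSum(x$cigar, c("M", "D", "N", "=", "X"))
  soft <- .cigarOpSum(x$cigar, c("S", "I"))
  nm <- x$tag$NM
  identity <- ifelse(unmapped | alen == 0, NA_real_,
                     100 * (1 - nm / alen))
  glen <- unname(hdr[gene])
  extends <- !unmapped & !is.na(glen) & (x$pos + refSpan - 1L > glen)

  data.frame(
    read_id = x$qname,
    mate = mate,
    gene_id = gene,
    identity_pct = round(identity, 4),
    align_len = ifelse(unmapped, 0L, alen),
    mapq = ifelse(unmapped, 0L, x$mapq),
    nonaligned_bases = ifelse(unmapped, 0L, soft),
    extends_beyond_gene = extends,
    stringsAsFactors = FALSE
  )
}

#' Write alignment records as a SAM file
#'
#' The inverse of [readAlignmentsSam()] for simulated records: aligned
#' reads are placed on their gene with CIGAR `<align_len>M<nonaligned>S`,
#' an NM tag reconstructing the percent identity, and a start position of
#' 1 (or past the gene end minus the alignment for records flagged as
#' extending beyond the gene). Records without a gene become unmapped SAM
#' lines.
#'
#' @param alignments alignment-record data.frame.
#' @param catalog an [MgsCatalog-class] providing gene lengths for the
#'   `@SQ` header.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeSamFile <- function(alignments, catalog, file) {
  genes <- geneInfo(catalog)
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id, genes$length), con)
  a <- alignments
  hasGene <- !is.na(a$gene_id)
  glen <- genes$length[match(a$gene_id, genes$gene_id)]
  flag <- 1L + ifelse(a$mate == 2L, 128L, 64L) + ifelse(hasGene, 0L, 4L)
  pos <- ifelse(hasGene,
                ifelse(a$extends_beyond_gene,
                       pmax(1L, glen - a$align_len + 2L), 1L), 0L)
  nm <- ifelse(hasGene, round(a$align_len * (1 - a$identity_pct / 100)), 0L)
  cigar <- ifelse(!hasGene, "*",
                  ifelse(a$nonaligned_bases > 0,
                         sprintf("%dM%dS", a$align_len, a$nonaligned_bases),
                         sprintf("%dM", a$align_len)))
  qlen <- ifelse(hasGene, a$align_len + a$nonaligned_bases, 100L)
  seqs <- vapply(qlen, function(n) strrep("A", n), character(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                   a$read_id, flag,
                   ifelse(hasGene, a$gene_id, "*"), pos,
                   ifelse(hasGene, a$mapq, 0L), cigar, seqs, nm)
  writeLines(lines, con)
  invisible(file)
}
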