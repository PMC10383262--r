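# shared fixtures and independent oracles, all built in code

# one alignment record row with passing defaults
alnRecord <- function(read_id = "r1", mate = 1L, gene_id = "g1",
                      identity_pct = 98, align_len = 120, mapq = 30,
                      nonaligned_bases = 2, extends_beyond_gene = FALSE) {
  data.frame(read_id = read_id, mate = mate, gene_id = gene_id,
             identity_pct = identity_pct, align_len = align_len,
             mapq = mapq, nonaligned_bases = nonaligned_bases,
             extends_beyond_gene = extends_beyond_gene,
             stringsAsFactors = FALSE)
}

# a record engineered to land on a given read status
recordWithStatus <- function(status, read_id, mate, gene_id = "g1") {
  switch(status,
    UNIQUE = alnRecord(read_id, mate, gene_id, mapq = 30),
    MULTI = alnRecord(read_id, mate, gene_id, mapq = 5),
    UNMAPPED = alnRecord(read_id, mate, gene_id, identity_pct = 80))
}

# direct transcription of the pair-category definition, used as the
# enumeration oracle for classifyPairs
oraclePairCategory <- function(s1, s2, g1, g2, geneToMgs) {
  if (s1 == "UNMAPPED" && s2 == "UNMAPPED") return("UNMAPPED")
  if (s1 != "UNIQUE" && s2 != "UNIQUE") return("MULTI")
  if (s1 == "UNIQUE" && s2 != "UNIQUE") return("MAPPED")
  if (s2 == "UNIQUE" && s1 != "UNIQUE") return("MAPPED")
  if (g1 == g2) return("MAPPED")
  if (geneToMgs[[g1]] == geneToMgs[[g2]]) return("MAPPED")
  "DISCORDANT"
}

# exact two-sided Mann-Whitney by complete enumeration of group labelings
# (tie-free data), following the convention of doubling the attained tail
oracleExactMW <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  uOf <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))
  }
  uObs <- uOf(seq_len(nx))
  uAll <- apply(utils::combn(nx + ny, nx), 2, uOf)
  tail <- if (uObs > nx * ny / 2) mean(uAll >= uObs) else mean(uAll <= uObs)
  list(U = uObs, p = min(1, 2 * tail))
}

oracleCliffsDelta <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# brute-force weighted UniFrac: per-branch descendant sets via tip paths
oracleWeightedUnifrac <- function(a, b, tree) {
  a <- a / sum(a); b <- b / sum(b)
  nTip <- length(tree$tip.label)
  tot <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    tips <- if (child <= nTip) child else {
      # all tips below the internal node
      desc <- child
      repeat {
        more <- tree$edge[tree$edge[, 1] %in% desc, 2]
        new <- setdiff(c(desc, more), desc)
        if (!length(new)) break
        desc <- c(desc, new)
      }
      desc[desc <= nTip]
    }
    lab <- tree$tip.label[tips]
    tot <- tot + tree$edge.length[k] * abs(sum(a[lab]) - sum(b[lab]))
  }
  tot
}
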