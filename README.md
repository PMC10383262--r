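# mgskit

Signature-gene metagenomic species (MGS) profiling and cohort contrast
statistics for shotgun metagenomes, in R.

## The problem

Shotgun-metagenomics studies of the infant gut — for example, comparing
breastfed infants with infants fed formula with or without human milk
oligosaccharides (HMOs) — quantify the community by mapping read pairs to
a reference gene catalog partitioned into *metagenomic species* (MGS).
Each MGS is quantified through a fixed set of ~100 signature genes, then
annotated taxonomically and functionally, and feeding groups are compared
per time point with nonparametric statistics. mgskit implements this
pipeline end to end, from alignment records to report tables, for anyone
who needs a transparent, testable implementation of the MGS workflow —
plus a synthetic cohort generator so every stage can be validated by
parameter recovery.

## What it computes

* **Read/pair classification** — a read is uniquely mapped at identity
  ≥ 95% over ≥ 100 bp with MAPQ ≥ 20; multi-mapped if only MAPQ fails;
  unmapped with > 10 nonaligned bases, bases beyond the gene, or failed
  identity/length. Pairs become `MAPPED` / `MULTI` / `UNMAPPED` (plus an
  explicit `DISCORDANT` class for unique hits to two different MGS), and
  uniquely mapped pairs form the gene count matrix.
* **MGS profiling** — per-sample MGS score
  `s_m = Σ_{g ∈ sig(m)} c_g / max(1, L_g − f + 1)` over signature genes
  (fragment length f = 350 bp), detection at ≥ 3 signature genes hit,
  sample-wise closure to relative abundances.
* **Taxonomy** — eight-rank tiered annotation from BLAST-style hit tables
  (support 75/75/60/50/40/30/25/20%, conflict ≤ 10/10/10/20/20/20/20/15%,
  rank-specific identity 95…45%), with a lineage-consistency pass.
* **Function** — Gut Metabolic Modules as reaction paths of KO steps
  (all steps if < 4 steps, two-thirds otherwise; manually curated fucose
  and sialic-acid modules at three-fifths), module abundance sums, an
  ALDH+/ALDH− split of *Bifidobacterium* and configurable species-group
  sums (opportunistic pathogens).
* **Ecology** — rarefaction without replacement, richness and Shannon
  index, a taxonomy-derived tree with weighted UniFrac
  `d(A,B) = Σ_b ℓ_b |A_b − B_b|`, PCoA, PERMANOVA (vegan, 1000
  permutations).
* **Contrasts** — Mann–Whitney U (exact for small tie-free samples),
  Cliff's delta, Benjamini–Hochberg FDR ≤ 10% per time point, with
  small-cell exclusion (n < 3) and heat-map/ordination export tables.

## Worked example

```r
library(mgskit); library(SummarizedExperiment)

catalog <- generateCatalog(nMgs = 8, genesPerMgs = 30, signatureSize = 20,
                           seed = 1)
design  <- cohortDesign(timepoints = "Week 1", nPerCell = 10)
truth   <- generateCohort(catalog, design, effectSpec(), seed = 1)
aln     <- simulateAlignments(truth, catalog, depth = 5000, seed = 1)
gc      <- buildGeneCounts(aln, catalog)
head(gc$summary, 3)
#>   sample pairs MAPPED MULTI UNMAPPED DISCORDANT
#> 1  S0001  5000   4250   250      500          0
#> 2  S0002  5000   4250   250      500          0
#> 3  S0003  5000   4250   250      500          0
```

Each sample's 5000 simulated pairs split into the four categories exactly
as the generator's noise fractions dictate (5% multi-mapped, 10%
unmapped). Profiling and group comparison:

```r
prof <- profileMgs(gc$counts, catalog)
ann  <- annotateMgs(catalog, simulateGeneHits(catalog, seed = 1))
d    <- weightedUnifrac(assay(prof, "abundance"), taxonomyTree(ann))
ss   <- as.data.frame(colData(truth))
unlist(permanovaTest(d, ss$group, nPerm = 999, seed = 1)[c("R2", "F", "p")])
#>       R2        F        p
#> 0.110299 1.673637 0.099000

byGenus <- aggregateByRank(assay(prof, "abundance"), ann, "genus")
ct <- contrastTable(byGenus, ss)
ct[ct$feature == "Bifidobacterium",
   c("group1", "group2", "p", "cliffs_delta", "q", "significant")]
#>   group1 group2          p cliffs_delta          q significant
#> 1     BM   5HMO 0.76228213         0.09 0.76228213       FALSE
#> 3     BM     IF 0.04515457         0.54 0.09603315        TRUE
#> 5   5HMO     IF 0.06402210         0.50 0.09603315        TRUE
```

The generator plants a +2 log-unit *Bifidobacterium* enrichment in the BM
and 5HMO groups; even at n = 10 per group the contrast table recovers it —
large positive Cliff's deltas against the control formula group, no signal
between the two enriched groups — and the BH-adjusted q values flag both
enriched-vs-control comparisons at the 10% FDR target.

## Package layout

* `R/` — synthetic data (`generateCatalog`, `generateCohort`,
  `simulateAlignments`), classification (`classifyReads`,
  `classifyPairs`, `buildGeneCounts`), profiling (`profileMgs`),
  annotation (`annotateMgs`), function (`assignModule`,
  `moduleAbundance`, `aldhPartition`), ecology (`weightedUnifrac`,
  `pcoaOrdination`, `permanovaTest`) and contrasts (`contrastTable`,
  `heatmapExport`).
* `vignettes/mgs-profiling-methods.Rmd` — the models, parameter choices
  and design decisions in detail.
* `inst/extdata/gmm_modules.txt` — curated module subset (synthetic
  stand-in for the full 103-module catalog; bring your own file for the
  complete set).
* `tests/testthat/` — unit, property and end-to-end validation suites
  built on independent oracles (enumeration, brute force, closed forms,
  calibration simulations).
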