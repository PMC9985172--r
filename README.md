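# bryostruct

Comparative genome-structure statistics for haploid plant genomes, built
around the questions raised by Marchantiopsida liverworts: how many genes
are duplicated, how fast does gene collinearity decay, when did
transposable elements amplify, and what happened to the U/V sex
chromosomes.  Liverwort genomes are small, with conserved chromosome
numbers, no known ancient whole-genome duplications, and dimorphic U
(female) / V (male) sex chromosomes; quantifying their structural
evolution needs a handful of statistics that this package implements as
composable R functions, together with a seeded genome-evolution simulator
that provides exact ground truth for testing every one of them.

## What it computes

* **Duplicate genes** — all-vs-all protein comparison (shared 5-mer
  prefilter, then local BLOSUM62 alignment) yields paralog pairs; the
  percent-duplicated statistic is `100 * n_duplicated / n_eligible`,
  where only genes with proteins strictly longer than 150 aa are
  eligible.  Pairs on the same scaffold with at most `tandem_max_intervening`
  genes between them are *tandem*, all others *dispersed*.

* **Collinearity** — single-copy ortholog pairs become anchors in gene
  rank space.  Blocks are chained under the two classical knobs *s*
  (minimum anchors per block) and *m* (maximum gap, in intervening gene
  ranks on each genome, between consecutive anchors): the
  maximum-anchor-count chain with consistent orientation is extracted
  repeatedly until none with ≥ *s* anchors remains.
  `percent_collinear = 100 · anchors_in_blocks / anchors`.  Minus-oriented
  blocks are the signature of inversions; `assign_scaffolds()` maps
  fragmented-assembly scaffolds onto reference chromosomes by modal
  ortholog hits (≥ 10 hits required); `decay_curve()` averages
  collinearity per divergence time.

* **TE divergence landscapes** — per-copy divergence from the family
  consensus is the Kimura 2-parameter distance (transitions and
  transversions separated; indel columns excluded; p-distance optional).
  `bin_landscape()` sums masked bp into 1% divergence bins per
  superfamily; `detect_bursts()` finds amplification episodes as
  prominent local maxima of a bp-weighted kernel density;
  `skewness_weighted()` compares distribution shape between genomes;
  `call_full_length()` classifies LTR retrotransposons as full-length
  (both LTRs ≥ 100 bp at ≥ 85% identity), solo, or truncated.

* **Gametologs** — for each locus a quartet tree (query ortholog, U and V
  gametologs, outgroup; neighbor joining on K2P distances) is classified
  by its internal split: the query is **U** if it pairs with the U
  gametolog, **V** with the V gametolog, and **O** (outgroup
  relationship) when the two gametologs pair with each other.
  Genomic placement is decided by presence in the female and male genome
  assemblies (seed-and-extend search, ≥ 95% identity over ≥ 80% of the
  query): female-only → U-linked, male-only → V-linked, both → autosomal.
  A locus whose ortholog is phylogenetically U, genomically autosomal,
  and has no detectable V ortholog is a **U→autosome translocation
  candidate** (the corresponding V gametologs are expected lost, per
  Muller's ratchet).

* **Simulator** — `simulate_genomes()`, `simulate_te_copies()` and
  `simulate_sex_loci()` generate two lineages diverged from a common
  ancestral gene order through logged inversions / translocations /
  duplications / losses, TE copy populations from configured burst
  episodes, and gametolog loci with optional planted translocations —
  all with truth tables, byte-reproducible from the seed.

## Worked example

```r
library(bryostruct)

cfg <- sim_config(seed = 42, n_chromosomes = 5, genes_per_chromosome = 200,
                  n_inversions = 20, n_translocations = 2,
                  n_tandem_dups = 5, n_dispersed_dups = 5, n_losses = 5)
sim <- simulate_genomes(cfg, sequences = FALSE)
anchors <- build_anchors(sim$anchors, sim$lineages$A$genes,
                         sim$lineages$B$genes)
blocks <- chain_blocks(anchors, s = 5, m = 25)
blocks
#> Collinear blocks (s = 5, m = 25): 30 block(s), 957/990 anchors chained (96.7%)
head(count_inversions(blocks), 3)
#>   scaffold_a scaffold_b n_plus n_minus
#> 1       chr1       chr1      1       8
#> 2       chr2       chr1      1       0
#> 3       chr2       chr2      1       5
```

990 single-copy ortholog anchors survive the planted events; 96.7% of
them sit in collinear blocks at the default *s* = 5, *m* = 25, and the
minus-oriented blocks per chromosome pair reflect the planted inversions
(the chr2–chr1 row comes from a translocated segment landing on chr1).
The same objects feed `percent_collinear()`, `assign_scaffolds()` and
`decay_curve()` for real anchor tables read with `read_anchor_table()`
and ranked annotations from `read_gff3()` + `rank_genes()`.

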