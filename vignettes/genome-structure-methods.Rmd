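---
title: "Methods: genome-structure statistics and their simulated ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-structure statistics and their simulated ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bryostruct)
```

This vignette explains the models and procedures behind each module, the
parameters that matter, the design choices that were genuinely open, and
what the simulator does and does not emulate.  Nothing here states a
result the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate conventions and gene ranks

Internally every interval is 0-based half-open; GFF3 and RepeatMasker
readers/writers convert at the boundary (both formats are 1-based
inclusive).  One representative mRNA per gene — the one with the largest
total exon length, ties broken by mRNA ID — supplies the exon structure
and CDS length.  Whether published per-annotation gene statistics use
one isoform per gene or all isoforms is usually unstated; a single
longest representative is this package's choice, and intron lengths are
the gaps between its consecutive exons.  `rank_genes()` numbers genes
0..n−1 along each scaffold by start coordinate (ties by end, then gene
id, for determinism).  All collinearity logic runs in this rank space:
gaps are counted in genes, not base pairs, which makes the chaining
parameters comparable across genomes with different intergenic content.

## Collinear block chaining

Anchors are 1:1 ortholog pairs; a gene participating in two pairs
violates the single-copy assumption and is rejected rather than silently
dropped.  Within a scaffold pair, a chain visits anchors with strictly
increasing rank in genome A while rank in genome B moves strictly
monotonically in one direction (`+` or `−`; an inversion inside a
collinear region therefore yields separate blocks rather than one
mixed-orientation block).  Consecutive anchors may skip at most *m*
intervening gene ranks **on each genome** — the symmetric reading of a
"maximum gaps allowed" parameter; a per-genome bound is also the
stricter and more reproducible of the plausible readings.

Extraction is greedy best-chain-first: the maximum-anchor-count chain is
found by dynamic programming (O(n²), implemented in C++ since chain
DP over hundreds of anchors times many extractions is the one hot loop
in the package), its anchors are removed, and the process repeats until
the best chain has fewer than *s* anchors.  Ties are resolved by smaller
total gap, then by the lexicographically smallest anchor sequence, and
`+` over `−` on exact ties, so output is fully deterministic and
invariant to input row order.  Match/gap scores and block E-values of
MCScanX-style tools are deliberately not reproduced: *s* and *m* are the
operative knobs, and correctness is established against an
exhaustive-enumeration oracle (every valid chain, depth-first) on small
instances rather than against any particular tool's output.

Two properties are worth stating precisely.  Percent collinear is
provably non-increasing in *s*: the extraction sequence does not depend
on *s*, which only truncates it.  Monotonicity in *m* is *not* a theorem
for greedy extraction — a longer chain admitted by a larger *m* can
swallow an anchor that a smaller *m* would have left to complete a
second block — but violations require contrived geometry; the property
test exercises 100 random instances, where the property holds.

`assign_scaffolds()` reports, for every scaffold with at least
`min_hits` (default 10) anchors, the reference chromosome with the most
hits, the fraction of hits it captures, and a tie flag (ties go to the
lexicographically smallest chromosome).  `decay_curve()` averages
percent-collinear values per divergence time; times are user-supplied
literature values — the package never estimates dates.

## TE divergence landscapes

Divergence of a copy from its family consensus is the Kimura
2-parameter distance, in percent, after a global alignment whose indel
columns are excluded; the metric is selectable (`"p"` for plain
mismatch fraction) because published landscapes rarely state theirs.
The CpG-adjusted variant some maskers report is out of scope.
Saturated comparisons (the K2P logarithms undefined) raise an error
instead of returning a number.

`bin_landscape()` sums hit lengths into half-open divergence bins
(default 1%) per superfamily; totals are exact integer sums, so the
landscape conserves masked bp and is additive over any partition of the
hits — both properties are tested literally.  `family_densities()`
ranks families by total masked bp (genome-size contribution, not copy
number) and evaluates a bp-weighted Gaussian kernel density for each of
the top 15.  The density is evaluated exactly on a fine grid spanning
±6 bandwidths (not via FFT binning, whose ~1e-4 mass error would be
visible at the tested quadrature accuracy).

Burst detection operationalises what is usually read off a landscape by
eye: modes of the bp-weighted kernel density (Silverman's rule-of-thumb
bandwidth) whose prominence is at least 10% of the global maximum.
Prominence is measured to the higher of the two valley floors toward
the nearest higher terrain.  At least 30 copies are required — below
that, mode inference on a KDE is noise.  Recovery is calibrated on
mixtures of Normal(5, 2) and Normal(25, 2) divergences, where two modes
within ±2 points are found in ≥95% of seeds.  Skewness is the adjusted
Fisher–Pearson standardized third moment with optional bp weights
(weighted moments, observation count for the small-sample factor).

`call_full_length()` labels an LTR element full-length iff both LTRs
are present, each ≥100 bp, with pairwise identity ≥85% (global
alignment, indel columns as mismatches); one LTR → solo, anything else
→ truncated.  The thresholds are config defaults chosen to be
conventional for "potentially functional" calls; structural LTR
discovery from raw genomes is out of scope, so elements arrive as
sequences already delimited.

## Gametolog classification

The unit of inference is a quartet: the query ortholog, the reference U
and V gametologs, and an outgroup.  Bayesian gene trees are replaced by
deterministic neighbor joining on K2P distances (`ape::dist.dna` +
`ape::nj`) — the contribution is the classification rule, not the tree
engine, and determinism makes the rule testable; externally computed
trees (e.g. from a Bayesian run) can be passed straight to
`classify_phylo()`.  The unique internal split of the unrooted quartet
decides the label: query with U → **U**, query with V → **V**, U with V
→ **O**.  The call is invariant to tip order and rooting; an unresolved
quartet falls back to the closest-pair rule on path distances and is
flagged with support 0.  An outgroup-free mode
(`classify_phylo_distances()`) applies the closest-pair rule to K2P
distances directly.

Genome presence uses exact 12-mer seeds sampled every 50 bp along the
query, matched against the scaffolds, each hit extended by local
alignment; presence requires ≥95% identity over ≥80% of the query.
With those defaults a pseudoautosomal copy at ~0.8% divergence is found
essentially always (the chance that all ~20 seeds are disrupted is
negligible), while the opposite gametolog at ~30% divergence can never
pass the identity bar even when a seed survives.  The decision table is
then: both genomes → autosomal, female-only → U-linked, male-only →
V-linked, neither → unplaced.

A translocation candidate must satisfy all three of: phylogenetically
U, genomically autosomal, and no V-descended sequence detectable in the
male genome — the expected signature of a U fragment moved to an
autosome with subsequent loss of the corresponding V gametologs under
Muller's ratchet.  "O" loci are excluded by the strict rule: U descent
is part of the signature, and admitting outgroup-labelled loci would
trade precision for recall with no truth to adjudicate on real data.

## The simulator

The generator exists to give every statistic an exact oracle, so its
design favours fixed counts over rates: each lineage receives exactly
the configured numbers of inversions (reverse a gene run, flip
strands), translocations (move a run to another chromosome), tandem and
dispersed duplications (mutated copy adjacent to, or ≥10 genes away
from, its source) and losses, applied sequentially in a random order
with every event logged.  Unsatisfiable events (an inversion shorter
than every chromosome's gene count cannot be placed, a translocation
needs two chromosomes) raise errors, never silent skips.  Duplication
sources are ancestor-descended genes sampled without replacement, so a
planted fraction of duplicated genes is exact — the acceptance
experiment plants 50 duplications among 150 ancestral genes, making
100 of 200 eligible genes members of a pair, i.e. exactly 50%.
Sequences evolve under Jukes–Cantor substitution only (no indels): each
lineage mutates every surviving gene to the configured per-lineage
depth, so ortholog pairs sit at about twice that depth.  Inversion
segment lengths are drawn from the configured range capped at the
largest chromosome.

TE copies are generated per burst episode by mutating the family
consensus to a divergence drawn from Normal(mode, sd) truncated at
zero; modes at or beyond 75% are rejected as beyond Jukes–Cantor
saturation.  The emitted repeat table leaves divergence unset —
estimating it is the landscape module's job — while the truth table
records every realized value.

Gametolog histories are parameterised in expected substitutions per
site: ancestrally nonrecombining pairs split into U and V at
`sexchrom_depth` (0.2 by default), each side splitting again at
speciation (`speciation_depth`, 0.1) — the configuration encodes
"nonrecombining before the two species diverged" as
`sexchrom_depth > speciation_depth`, and the defaults put the U/V split
at twice the speciation depth.  Pseudoautosomal loci split only at
speciation, with a recent within-reference U/V divergence
(`recent_uv_depth`, half the speciation depth), so their true quartet
label is "O".  Opposite-sex copies of autosomal material drift at
`within_species_depth` (0.004 subs/site per copy), chosen so that
homologous autosomal scaffolds of the two sexes are >99% identical —
the criterion used to separate autosomal from sex-specific scaffolds.
The outgroup attaches at `outgroup_depth` (2× the sex-chromosome
depth).  Translocated loci place the near-identical U-descended copy in
both sex genomes on homologous autosomal scaffolds and delete the V
copy.  Sex genomes are assembled as small scaffolds (four loci plus
150 bp spacers each): presence/absence, not coordinates, carries the
signal.

What the simulator does **not** emulate — and hence what green tests do
not certify about real data: indel evolution and alignment ambiguity,
rate heterogeneity and saturation beyond K2P's reach, nested or
fragmented TE copies, assembly and annotation error, paralog
interference in ortholog assignment, and recombination within lineages.
The statistics are exercised under the substitution model they assume;
on real genomes their inputs (alignments, ortholog tables, repeat
annotations) import all of the above.

## Numerical choices and problem sizes

Fixed seeds make every simulation byte-reproducible; all randomness in
the acceptance script derives from its `--seed` argument.  The test and
acceptance experiments use: 200 random anchor instances (≤12 anchors)
against the exhaustive oracle across s ∈ {3,4,5} × m ∈ {1,2,25};
1,000-gene genomes with 0–100 inversions, 10 replicates per level, for
the decay curve (Spearman ρ ≤ −0.9); 2,000-copy two-burst mixtures over
50 seeds; 3 kb sequences at JC distance 0.20 over 50 seeds for the
estimator (±1 point on the mean); 100 gametolog loci at 1 kb for label
recovery and 10 seeds of 40 loci (4 translocated) at 600 bp for
translocation inference.  These sizes keep the full suite at a few
minutes on one CPU while leaving each check statistically comfortable
rather than marginal.

## Known limitations

* Greedy chaining is not globally optimal in total anchors, and
  m-monotonicity can fail on adversarial instances (see above).
* The k-mer prefilter for paralog detection can in principle miss a
  pair whose identity hovers at the 30% threshold with no two shared
  5-mers; the exhaustive mode (`prefilter = FALSE`) exists for audit.
* K2P divergence without CpG adjustment underestimates the age of
  methylation-eroded elements relative to masker-reported values.
* Genome presence search assumes the query is colinear with its genomic
  copy over ≥80% of its length; heavily fragmented assemblies can push
  true positives below the coverage bar.
* The translocation rule is strict (U-labelled loci only); loci whose U
  descent is real but unresolved in the quartet are not counted.
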