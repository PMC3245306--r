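---
title: "Classifying gene ancestry from BLAST hit neighborhoods"
author: "azohgt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene ancestry from BLAST hit neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azohgt)
```

## The problem

*Azospirillum* are plant-growth-promoting rhizobacteria whose closest
relatives (the family *Rhodospirillaceae*, order *Rhodospirillales*) are
mostly aquatic. A transition from water to the rhizosphere of land
plants leaves a genomic signature: genes inherited vertically from the
aquatic ancestor still find their closest database matches among
*Rhodospirillaceae*, while genes acquired horizontally from co-resident
soil and plant-associated bacteria best-match distant taxa such as
*Rhizobiales* or *Burkholderiales*. `azohgt` implements a classifier
that turns this signature into per-gene calls, plus the downstream
summaries, proteomics formulas and genome statistics that accompany such
an analysis, and simulators that make every stage testable without any
sequence database.

## The neighborhood model

Each protein query is BLASTed against a non-redundant genome set; the
classifier never re-runs BLAST but consumes tabular hit files. Hits are
filtered at E-value 1e-4, hits to the query's own species are removed,
and only the first occurrence of each (binomial) species is kept, in
BLAST output order. The resulting ordered species list is the
**neighborhood**; each entry carries one of four memberships:

* `G` — another species of the focal genus (*Azospirillum*),
* `F` — focal family (*Rhodospirillaceae*) outside the genus,
* `O` — focal order (*Rhodospirillales*) outside the family,
* `X` — outside the order.

The rules only read rank order and membership, never scores. The top-8
window is not arbitrary: excluding the query organism, the database
holds exactly 8 other family genomes (2 *Azospirillum*, 3
*Magnetospirillum*, 2 *Rhodospirillum*, *Nisaea*), so a fully vertical
gene can fill the window with family species.

Eight outcomes are possible — ancestral or horizontally transferred
(HGT) at high, medium or low confidence, plus unassigned:

| rule | condition |
|---|---|
| ancestral, high | ≥ 6 of the top 8 species in the focal order; "all but 1" when fewer than 8 species exist |
| hgt, high | 0 focal-order species in the top 10, genus excluded |
| conflict → unassigned | simultaneously hgt-medium and ancestral-medium-or-low |
| ancestral, medium | ≥ 4 focal-family species in the top 8 |
| hgt, medium | 0 focal-order species in the top 5, genus excluded |
| ancestral, low | ≥ 1 focal-family species in the top 8, genus excluded |
| hgt, low | 0 focal-family species in the top 8, genus excluded |
| unassigned | no hits outside the focal genus (incl. no hits at all) |

"Genus excluded" removes other *Azospirillum* species from the ordered
list *before* the window is taken (`genusExclusion = "prefilter"`),
so genus hits cannot occupy window slots and mask distal evidence; an
`"inwindow"` mode that keeps the slots is available for comparison.

```{r rules}
classifyMembership(c("F", "F", "O", "F", "F", "F", "X", "X"))[1:3]
classifyMembership(rep("X", 10))[1:3]
classifyMembership(c("X", "X", "X", "X", "X", "F", "X", "X"))[1:3]
```

## Design choices in the rule engine

The rule sentences do not fix an evaluation order, so the engine makes
the following choices, all of which the exhaustive sweep (below)
documents:

* **Precedence**: ancestral-high → hgt-high → conflict → ancestral-medium
  → hgt-medium → ancestral-low → hgt-low → unassigned. Stronger evidence
  wins; the conflict clause is checked *before* ancestral-medium because
  a gene that is simultaneously hgt-medium and ancestral-medium must end
  up unassigned, which a later check could never produce. Such inputs
  are reachable only through genus-heavy neighborhoods (e.g. 4 `G` in
  the top 8 with no order member among the first 5 non-genus species).
* **Empty-after-genus-removal first**: a neighborhood containing only
  focal-genus species is unassigned even when it would satisfy the
  ancestral-high tally — "no hits outside the genus" is treated as the
  stronger statement.
* **"All but 1" floor**: read literally, a single outside-order hit
  would satisfy "all but 1 of fewer than 8 species" (0 ≥ 0). The engine
  additionally requires at least one focal-order species for the
  short-list ancestral-high rule; a one-species neighborhood of one `X`
  falls through to hgt-high instead.
* **Genus counting**: other focal-genus species count toward the
  ancestral-high and ancestral-medium tallies by default
  (`countFocalGenusInAncestral = TRUE`), consistent with the family
  inventory that motivates the window of 8; the flag flips the reading.
* **Species granularity**: deduplication is by binomial species name;
  strains collapse.

Queries with no hit table at all are reported unassigned with rule
`no_blast_hits`, distinguishable from `no_informative_hits`.

## Verification by exhaustive sweep

Because the input space is tiny — membership sequences over a 4-letter
alphabet — the rule engine can be verified exhaustively rather than by
sampling. `literalAncestryOracle()` is a deliberately naive, scalar,
sentence-by-sentence transcription of the rules kept independent of the
production engine; the test suite and the acceptance script compare the
two on **all 1,398,101 sequences of length ≤ 10** and additionally
assert, over the same enumeration, that the raw equal-tier conditions
are mutually exclusive (ancestral-high vs hgt-high under the
genus-not-counted reading, where it is a theorem; ancestral-low vs
hgt-low always). The batch engine `classifyMembershipMatrix()` used for
the sweep is itself checked against the scalar `classifyMembership()`
on thousands of random sequences, closing the chain.

## What the simulators emulate — and what they do not

`simulateTaxonomy()` reproduces the shape of the reference database
around the focal lineage: the query species, 2 other *Azospirillum*, 6
further family species, 3 order-level relatives (*Acetobacteraceae*),
and 8 outside-order species in each of three donor groups
(*Rhizobiales*, *Burkholderiales*, other; default mix 0.40/0.35/0.25,
chosen once as a plausible soil-donor profile). Every species carries
two strain-level subject keys so deduplication is exercised.

`simulateHitTables()` draws each gene ancestral or HGT with probability
`hgtFraction`. Ancestral genes lead with family species (each retained
with probability `familyRetention` = 0.9 by default, order preserved),
then order-level relatives, then outside species. HGT genes lead with a
donor group drawn from `donorGroupProbs`; their first 10 non-genus
species are always outside the order, with family hits only beyond rank
10. Every gene also best-hits its own genome, and species occasionally
contribute duplicate strain hits. E-values are a deterministic
decreasing function of rank (`10^(-100 + rank)`), since the rules never
read them beyond the cutoff.

The simulation is deliberately clean: it produces almost exclusively
high-confidence calls, which is what makes injected-fraction recovery a
sharp test (recovered high-confidence HGT fraction within ±0.05 of the
injected p for p in 0.1–0.7, and exactly the label in the p = 0, ρ = 1
and p = 1 limits). It does **not** emulate paralogy, contamination,
database bias, patchy taxon sampling or genuinely ambiguous
neighborhoods — the medium/low/conflict tiers are exercised by the
exhaustive sweep, not by the generator. Passing these tests shows the
rules and plumbing are implemented correctly, not that the biological
error rate on real genomes is small.

All generators are pure functions of `(SimConfig, seed)`; the caller's
RNG state is left untouched.

## Downstream summaries

* `cogEnrichment()` compares COG functional-category composition
  between the ancestral and HGT sets (high-confidence by default) with
  a two-sided Fisher's exact test per category and Benjamini–Hochberg
  adjustment (FDR 0.05 recorded in the output attributes). The test
  choice is this package's; the tests verify the p-values against
  exhaustive hypergeometric enumeration.
* `bestHitTaxonomy()` reads each HGT gene's donor proxy as its first
  hit outside the query species and focal genus — otherwise every best
  hit would be another *Azospirillum* and the distribution would be
  uninformative. Genes with no eligible hit land in an `unresolved`
  bin; fractions including that bin sum to 1. Grouping levels are the
  ones the taxonomy table carries (order, family, genus).
* `estimateDivergenceTime()` applies the 16S rRNA rule of thumb that
  1–2% divergence corresponds to 50 Myr: the 2% rate yields the
  minimum age, the 1% rate the maximum, so 8% divergence dates to
  200–400 Myr. The mapping is linear and exact; it is a rough
  approximation by construction, not a calibrated clock.

```{r clock}
estimateDivergenceTime(8)
```

## Proteomics formulas

`filterPsms()` applies the DTASelect-style criteria: XCorr ≥ 1.8 / 2.5 /
3.5 for charges +1 / +2 / +3 (charges above +3 use the +3 threshold and
are flagged), ΔCN ≥ 0.08, at-least-semi-tryptic status, and ≥ 2
distinct passing peptide sequences per identified protein (PSMs of the
same peptide count once; shared peptides count toward every protein).
Thresholds are read as inclusive minima — "filter level 1.8" admits
1.8. `fpRate()` is the doubled decoy fraction
`200·nRev/(nRev + nReal)`; `nsaf()` computes
`(SpC/L)_k / Σ(SpC/L)` with the sum-to-1 invariant checked to 1e-9.

## Genome statistics and in-silico PCR

`computeGenomeStats()` counts typed features and computes GC over
unambiguous bases only (stable under N-padding), rounded half-even to 2
decimals. The protein-coding fraction is reported both as the per-base
union of CDS intervals (overlaps merged per replicon) and as the raw
length sum, because annotation pipelines differ on the definition;
for this reason the coding fraction is treated as descriptive output
rather than a reference value. rRNA genes are counted individually; no
operon clustering is attempted. `insilicoPcr()` reports every exact
placement of a primer pair on either strand within a product-size cap,
primers included in the product length; the bundled default primer pair
is the 19-mer pair whose genomic product is 211 bp, used as a planted
ground-truth check. Zero mismatches only; degenerate primers are out of
scope.

## Problem sizes and numerical conventions

The exhaustive sweep covers lengths 0–10 (1.4M sequences); recovery
runs use 1000 genes × 20 replicates per injected fraction; limit cases
300 genes; PSM simulations 500 spectra; simulated replicons 5 kb. These
sizes make every distributional claim testable to the stated tolerances
while keeping a full run in minutes. Ties in CheA class scores are
broken lexicographically with a warning; flat-file coordinates are
1-based inclusive; compound feature locations collapse to their
min/max envelope with strand from `complement`; parsing is
locale-independent and scientific-notation e-values are accepted in
either case.

## Known limitations

* Real-genome reproduction of the published ancestry proportions
  requires the original ~650-genome BLAST database, which is not
  recoverable; the package validates the method, not those numbers.
* The flat-file reader targets the common GenBank/EMBL feature-table
  subset (single record, envelope locations); it is not a full-fidelity
  parser and writing flat files is out of scope.
* The classifier trusts hit-file order; it never re-sorts, so a
  re-sorted input silently changes windows — by design, since the
  published windows are defined by BLAST output order.
* Protein grouping/parsimony, spectrum searching, tree-based HGT
  validation and donor identification beyond best-hit tallies are out
  of scope.
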