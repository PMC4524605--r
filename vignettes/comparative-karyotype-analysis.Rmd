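---
title: "Comparative karyotype analysis: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative karyotype analysis: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoevol)
```

## The data model

The substrate of the analysis is a comparative gene-location table: one row
per cDNA probe, one column per species, each cell a cytogenetic address.
FISH mapping yields addresses at very different resolutions — banded
chromosomes give arm and band intervals (`2q12.2–q21.1`), unbanded ones give
only a chromosome number (`7`), microchromosomes are individually
indistinguishable (`Micro`), and in some karyotypes a gene can only be
placed on "one of the small chromosomes 11–18".  `parse_location()` captures
all of these as a `ChromLocation`-style record with explicit flags rather
than forcing them into a single coordinate system, and the rest of the
pipeline treats each resolution for what it is:

* **Band labels are ordinal, never metric.**  `11.1 < 11.2 < 12 < 21.1`
  along an arm, centromere to telomere; no physical distances are implied,
  so nothing downstream computes with band arithmetic.
* **The micro-group token (`11–18`) is a single pseudo-chromosome** meaning
  "a microchromosome, identity unknown".  Modelling it as eight
  alternatives would create spurious resolution the data do not have.
* **A band interval spanning the centromere** (e.g. `3p11.1–q11`) is
  assigned `arm = "whole"`; it supports chromosome-level but not arm-level
  statements.
* **Sex chromosomes written as numbered chromosomes** (`4 (ZW)`, `5 (Z)`)
  are stored under their numeric label with the sex annotation kept
  separately, so cross-species comparisons use one label per chromosome.
* **Acrocentrics named with and without an arm letter** (`13` vs `13q`)
  compare equal: an acrocentric is effectively one-armed.

## Conserved synteny and macrochromosome units

A synteny segment is a set of genes co-located on one chromosome/arm in each
of two species.  `segment_table()` reports every such segment with its
supporting genes; the minimum support for reporting is one gene — single-gene
homology statements are standard practice in comparative FISH work — but the
support count is always carried so callers can threshold.

Conservation against the chicken is scored with a configurable set of
avian macrochromosome units, by default GGA1p, 1q, 2p, 2q, 3, 4q, 5, 6, 7,
8 and Z.  GGA4p is deliberately excluded from the default set: its content
behaves as fused ancestral microchromosome material, and including it would
blur the macro/micro distinction the unit set exists to draw.  Arm-level
units require arm-level data: a gene mapped to chicken `2p` matches units
`2p` and `2`, but a gene mapped to bare `2` matches only unit `2`.

One documented discrepancy: the ten conserved gecko chromosomes connect to
eight numbered lacertid macrochromosomes through the unit set, yet gecko
chromosome 12 — macro-homologous through LRE6p — is not part of the
ten-chromosome set, because its genes (chicken chromosome 27) fall outside
the default units.  The package reproduces the published counting through
the unit rule and flags, rather than resolves, the question of why
chromosome 12 was counted out.

## Microchromosome origin

Evidence for microchromosomal origin comes from three microchromosome-rich
Toxicofera reference species (VSA, LRE, EQU).  Per gene and reference
species, a placement on a microchromosome counts as micro evidence and a
placement on an identified macrochromosome as macro evidence.  A chromosome
is classified:

* `all_micro` — at least **two** informative genes, each micro in **every**
  reference species with data for it;
* `mixed` — at least one micro and one macro evidence instance;
* `all_macro` — only macro evidence;
* `insufficient` — fewer than two informative genes.

The two-gene and unanimity requirements are deliberate: one gene cannot
distinguish a fused microchromosome from a short translocated segment, and a
single macro placement in any reference species (e.g. a gene sitting on the
snake's chromosome 1p) disqualifies a whole-chromosome micro-origin claim.
The green anole is excluded from the default evidence set because its
column is sparse and chromosome-number based; the set is configurable.

Lineage independence of microchromosome fusions is tested by
`lineage_partition_overlap()`: restricted to micro-derived markers mapped in
both lineages, the partition of markers into chromosomes is compared block
by block.  Identical partitions are expected under shared ancestral fusions;
the gecko and lacertid partitions differ (one lacertid chromosome's markers
split over two gecko chromosomes), the signature of independent fusion
histories.

## Event inference and polarization

The informative correspondence pattern is *arms-to-two-wholes*: a bi-armed
chromosome whose p and q arms each correspond to a distinct chromosome of
another species.  Whether this is a fusion (derived joined state) or a
fission (derived split state) is decided by outgroup parsimony on the fixed
study tree `(GGA,(GHO,(LAG,(VSA,LRE,EQU,ACA))))`, with the within-Toxicofera
relationships treated as a polytomy.  For each candidate, the two arms'
supporting marker sets are located in every species; a species is *joined*
if the plurality chromosome sets of the two marker sets intersect, *split*
if they are disjoint, *uninformative* otherwise (unidentified `Micro`
placements never inform).  The outgroup anchors the ancestral state; the
event lands on the stem branch of the smallest clade containing all
derived-state species, and the cheaper of the fusion and fission readings is
chosen.  Conflicting or insufficient evidence produces an unpolarized event
listing both readings instead of a branch.  Re-rooting the tree so the
formerly derived lineage is basal flips every polarized fusion into the dual
fission on the mirrored branch, with identical operands and evidence — a
property the test suite checks on simulated data.

Two further evidence channels complete the scenario:

* **Interstitial telomeric sites.**  An ITS is a relic of tandem fusion.
  An ITS on a chromosome whose micro-derived markers are confined to a
  single arm yields a tandem-fusion event joining that arm (a former
  microchromosome) to the acrocentric proto-chromosome formed by the rest.
* **Morphology.**  A bi-armed chromosome whose whole correspondence is one
  effectively-acrocentric partner chromosome is read as a centric fusion on
  the bi-armed lineage's branch, with the arm sharing fewer markers taken as
  the residual lineage-specific proto-chromosome.  This is the only rule
  that uses morphology rather than marker splits, and the alternatives
  (pericentric inversion, centromere repositioning) are recorded in the
  event note.  Centromere repositioning itself is representable as an event
  kind but never auto-inferred.

Events recovered from several species pairs are merged when their kind,
branch and operand marker sets agree; operand names follow the most basal
partner species, so ancestral operands read as proto-chromosomes of the
most conservative karyotype.  Output order is deterministic (branch,
product, kind), and tie-breaks are lexical throughout.

Inversions are handled conservatively.  On real fixtures the
within-chromosome gene order is only approximate (row order of the table,
mirroring the order drawn in published map figures), so order-based calls
are emitted as qualitative, unpolarized flags and never as minimal-event
claims.  Exact reversal distances — breadth-first search over the unsigned
permutation group, refused above n = 8 — are reserved for explicit-rank or
simulated data, where the oracle bounds
⌈breakpoints/2⌉ ≤ distance ≤ n − 1 are verified exhaustively up to n = 6.

## The simulator: what it emulates, and what it does not

`sim_evolve()` evolves a pseudo-haploid ancestral karyotype (default 19
acrocentric macrochromosomes and 12 microchromosomes — an illustrative
squamate-like complement; ancestral chromosome numbers for squamates are
not established, and the defaults are documented as such) along a species
tree.  Centric fusion joins two one-armed chromosomes into a bi-armed one;
fission splits a bi-armed chromosome at the centromere; tandem fusion
appends a microchromosome to an arm end and leaves an ITS with configurable
probability (default 1); inversion reverses a contiguous marker block.
Random operands are drawn uniformly from the currently eligible
chromosomes, fully seeded.  Tips report marker locations exactly as a FISH
map would: identified chromosomes with arm letters, microchromosomes as an
undifferentiated `Micro`, plus explicit rank columns so order-based
inference is exact on simulated data.

The generator intentionally omits sequence evolution, chromosome sizes,
recombination and translocations, and it simulates one copy per chromosome
pair without sex chromosomes.  Passing recovery tests therefore show that
the inference chain is sound *given* the event vocabulary and
identifiability of the data; they do not certify performance on phenomena
outside that vocabulary (e.g. reciprocal translocations) or on maps with
systematically misassigned locations.

Recovery is scored against the recorded ground truth: a simulated fusion
counts when an inferred fusion matches its branch and its operand marker
sets.  With three markers per ancestral macrochromosome, 1–3 random fusions
per derived branch on a five-tip tree, and 50 replicates, recovery exceeds
95%.  The residual misses are genuine identifiability limits, chiefly
homoplasy: when the same two chromosomes happen to fuse independently in
both members of a terminal sister pair, parsimony correctly — but, against a
ground truth of two events, unrecoverably — prefers a single stem fusion.

## Numerical and degenerate-input choices

* Plurality (not majority) chromosome sets decide joined/split states; ties
  make a species uninformative rather than forcing a call.
* Header-only tables parse to empty maps; maps restricted to a single
  species yield empty event lists; an empty unit set yields empty
  conserved sets (vacuous predicates stay vacuous).
* Serialisation normalises the dash dialect to an en-dash, so
  read–write–read round-trips are field-identical even when the source
  mixed hyphens and spacing.
* Problem sizes in the test suite (five-tip trees, 19 + 6 or fewer
  chromosomes, ≤ 3 markers per chromosome, 50 recovery replicates, full
  permutation enumeration to n = 6) were chosen so the whole suite runs in
  about a minute while still exercising every code path; they are the
  package's own choices, not statements about the method's limits.

## Known limitations

* Polarization treats within-Toxicofera structure as a polytomy; events
  shared by only part of that clade are placed on its stem rather than
  resolved further.
* The morphology-based fusion rule can fire on correspondences where a
  pericentric inversion or centromere repositioning is an equally
  parsimonious reading; the event note says so, and consumers who want
  marker-split-only inference can filter on it.
* Micro-derived marker partitions treat the micro-group pseudo-chromosome
  as one block, which can overstate partition identity when several
  unidentified small chromosomes are involved.
* Landmark positions (pericentromeric, proximal) are free-text notes, not
  coordinates; ITS placement within an arm is not modelled.
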