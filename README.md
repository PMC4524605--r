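# karyoevol

Comparative cytogenetic maps and karyotype rearrangement inference for
squamate reptiles.

## The problem

Most squamate reptiles carry a karyotype of a few large macrochromosomes plus
many dot-like microchromosomes, but two lineages — geckos (Gekkota) and
lacertid lizards — have few or none.  Did microchromosomes disappear by
repeated fusion in those lineages, or did they arise by fission elsewhere?
Comparative gene mapping answers this: the same cDNA probes FISH-mapped in
several species give, for each gene, a chromosomal address per species, and
co-located gene sets (conserved synteny segments) let one read fusion,
fission and inversion events off the species tree.

`karyoevol` implements that analysis as a reusable pipeline for people who
work with cytogenetic location tables:

* **Parsing** of the field's location dialect (`"2q12.2–q21.1"`, `"Micro"`,
  `"11–18"`, `"4 (ZW)"`, `"un"`, `"–"`) into structured records.
* **Synteny segments**: for a species pair, every (chromosome/arm,
  chromosome/arm) combination sharing mapped genes, with support counts.
* **Macrochromosome conservation**: which chromosomes of a species carry
  genes from the 11 avian macrochromosome units (GGA1p, 1q, 2p, 2q, 3, 4q,
  5, 6, 7, 8, Z), and which units are represented.
* **Microchromosome origin**: per-chromosome classification
  (`all_micro` / `mixed` / `all_macro` / `insufficient`) from the placements
  of its genes in microchromosome-rich reference species, and a comparison
  of micro-derived marker partitions between lineages.
* **Event inference**: centric fusions/fissions polarized by outgroup
  parsimony on a fixed tree (a chromosome whose two arms match two distinct
  chromosomes elsewhere is a fusion/fission candidate; the outgroup state
  decides the direction and the most parsimonious branch receives the
  event), tandem fusions evidenced by interstitial telomeric sites (ITS),
  and micro-fusion calls for chromosomes assembled from several ancestral
  microchromosomes.  Exact small-n reversal distances (BFS oracle) and
  breakpoint counts support inversion reasoning.
* **Simulation**: a karyotype-evolution generator that evolves an ancestral
  complement of acrocentric macro- and microchromosomes along a tree under
  fusion/fission/tandem-fusion/inversion events, records its ground truth,
  and scores how well the inference chain recovers it.

The package ships the comparative FISH map of 86 functional genes across the
Hokou gecko (GHO), sand lizard (LAG), water monitor (VSA), butterfly lizard
(LRE), Japanese four-striped rat snake (EQU), green anole (ACA) and chicken
(GGA), with the matching karyotype, landmark and species-tree fixtures.

## Worked example

```r
library(karyoevol)

map <- gecko_map()
map
#> Comparative cytogenetic map: 86 markers x 7 species
#> Species: GHO, LAG, VSA, LRE, EQU, ACA, GGA

conserved_macro_chromosomes(map, "GHO")
#> [1] "1"  "2"  "3"  "4"  "6"  "7"  "8"  "13" "14" "15"
hit_units(map, "GHO")
#> [1] "3"  "5"  "6"  "7"  "8"  "1p" "1q" "2p" "2q" "4q" "Z"
```

Ten gecko chromosomes carry genes from all 11 avian macrochromosome units —
the conserved-macrochromosome backbone.  Micro-origin accounting flags the
chromosomes assembled from ancestral microchromosomes:

```r
prof <- micro_origin_profile(map, "GHO", karyotypes = gecko_karyotypes())
prof$chromosome[prof$classification == "all_micro"]
#> [1] "5"  "9"  "10" "11"
```

Scenario inference reproduces the fusion history, e.g. (excerpt):

```r
ev <- infer_scenario(map, gecko_karyotypes(), gecko_landmarks(), gecko_tree())
ev
#> kind           branch     product          operands
#> centric_fusion Gekkota    GHO1             proto-LAG3 + proto-LAG2
#> centric_fusion Gekkota    GHO2             proto-GHO2q + proto-LAG1
#> tandem_fusion  Gekkota    GHO14            GHO14p + proto-GHO14q
#> centric_fusion Toxicofera EQU2/LRE2/VSA1   proto-GHO4 + proto-GHO1q
#> centric_fusion Toxicofera LRE3             proto-GHO15 + proto-GHO13
#> centric_fusion Toxicofera EQU3/LRE4        proto-GHO6 + proto-GHO3
#> centric_fusion Toxicofera EQU6/LRE5/VSA3   proto-GHO7 + proto-GHO14q
#> centric_fusion Toxicofera EQUZ/LRE6/VSA4   proto-GHO8 + proto-GHO12
#> ...
```

Read: the bi-armed butterfly-lizard chromosome 3 arose on the Toxicofera
branch by centric fusion of the two acrocentrics that survive as gecko
chromosomes 13 and 15; gecko chromosome 14 is a tandem fusion of a
microchromosome (now 14p) onto an acrocentric proto-14q, still marked by an
interstitial telomeric site.  Merged products (`EQU2/LRE2/VSA1`) are the
same ancestral fusion observed in several descendant species.

`run_reproduction()` recomputes every headline number against the packaged
expected-value table and reports pass/fail per check.  A thin command-line
front end is included at `inst/cli/karyoevol.R`
(`report`, `homology`, `rearrange`, `simulate` subcommands).

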