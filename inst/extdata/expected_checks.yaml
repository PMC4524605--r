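# Expected headline values recomputed by run_reproduction() from the packaged
# comparative map.  Each entry names the check and the value the pipeline is
# expected to reproduce from the fixture tables.
total_markers: 86
newly_mapped: 80
previously_mapped: 6
probes_cloned_from_gecko: 18
origin_tallies:
  GHO: 24
  LAG: 30
  LRE: 31
  EQU: 1
conserved_macro_chromosomes: ["1", "2", "3", "4", "6", "7", "8", "13", "14", "15"]
avian_units_hit: ["1p", "1q", "2p", "2q", "3", "4q", "5", "6", "7", "8", "Z"]
lacertid_macro_chromosomes: ["1", "3", "4", "5", "7", "8", "9", "10"]
gene_counts:
  "1": 9
  "3": 7
  "6": 5
  "7": 6
  "13": 6
gho7_all_on_gga4q: true
micro_composed: ["5", "9", "10", "11"]
partitions_identical_with_lacertid: false
fusion_products:
  Toxicofera: ["LRE2", "LRE3", "LRE4", "LRE5", "LRE6"]
  Gekkota: ["GHO1", "GHO2"]
tandem_fusion_products: ["GHO14"]
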