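test_that("segment tables recover the published per-chromosome homologies", {
  map <- .fx("map")
  sg <- segment_table(map, "GHO", "GGA")
  hit <- sg[sg$chrom_a == "7" & sg$chrom_b == "4" & sg$arm_b == "q", ]
  expect_equal(hit$support_count, 6L)

  sl <- segment_table(map, "GHO", "LRE")
  expect_true(any(sl$chrom_a == "13" & sl$chrom_b == "3" & sl$arm_b == "q"))

  expect_error(segment_table(map, "GHO", "GHO"), "different species")
})

test_that("a marker mapped in only one species yields no segment", {
  m <- read_map_text(c("symbol\torigin\tS1\tS2",
                       "g1\tS1\t1\t–"))
  expect_equal(nrow(segment_table(m, "S1", "S2")), 0L)
})

test_that("segment tables are symmetric and conserve support", {
  map <- .fx("map")
  pairs <- list(c("GHO", "LRE"), c("GHO", "LAG"), c("LAG", "GGA"))
  for (p in pairs) {
    ab <- segment_table(map, p[1], p[2])
    ba <- segment_table(map, p[2], p[1])
    key <- function(s, flip) {
      if (flip) paste(s$chrom_b, s$arm_b, s$chrom_a, s$arm_a)
      else paste(s$chrom_a, s$arm_a, s$chrom_b, s$arm_b)
    }
    expect_setequal(key(ab, FALSE), key(ba, TRUE))
    expect_equal(sum(ab$support_count), sum(ba$support_count))

    both <- intersect(
      map$locations$symbol[map$locations$species == p[1] &
                             map$locations$status == "mapped"],
      map$locations$symbol[map$locations$species == p[2] &
                             map$locations$status == "mapped"])
    expect_equal(sum(ab$support_count), length(both))
  }
})

test_that("symmetry and support conservation hold on random simulated maps", {
  tr <- sim_tree5()
  for (seed in 1:3) {
    set.seed(seed)
    bev <- list(S3 = list(list(kind = "centric_fusion"),
                          list(kind = "inversion")),
                N34 = list(list(kind = "centric_fusion")))
    cfg <- sim_config(n_macro = 8, n_micro = 4, markers_per_macro = 3,
                      markers_per_micro = 2, branch_events = bev,
                      seed = seed)
    sim <- sim_evolve(cfg, tr)
    ab <- segment_table(sim$map, "S1", "S3")
    ba <- segment_table(sim$map, "S3", "S1")
    expect_equal(sum(ab$support_count), sum(ba$support_count))
    expect_equal(sum(ab$support_count), nrow(sim$map$markers))
  }
})

test_that("conserved-macrochromosome scoring reproduces the ten-chromosome set", {
  map <- .fx("map")
  expect_equal(conserved_macro_chromosomes(map, "GHO"),
               c("1", "2", "3", "4", "6", "7", "8", "13", "14", "15"))
  expect_equal(conserved_macro_chromosomes(map, "GHO",
                                           units = character(0)),
               character(0))
  expect_equal(conserved_macro_chromosomes(map, "GHO", units = "4p"), "5")
  expect_equal(conserved_macro_chromosomes(map, "LAG"),
               c("1", "3", "4", "5", "7", "8", "9", "10"))
})

test_that("unit hits cover the avian unit set and are monotone", {
  map <- .fx("map")
  expect_setequal(hit_units(map, "GHO"), avian_macro_units())
  expect_equal(hit_units(map, "GHO", units = "Z"), "Z")
  expect_equal(hit_units(map, "GHO", units = character(0)), character(0))

  set.seed(11)
  full <- avian_macro_units()
  for (i in 1:5) {
    sub <- sample(full, sample(seq_along(full), 1))
    expect_true(all(conserved_macro_chromosomes(map, "GHO", units = sub)
                    %in% conserved_macro_chromosomes(map, "GHO")))
  }
})

test_that("micro-origin profiles classify chromosomes as published", {
  map <- .fx("map"); k <- .fx("karyotypes")
  prof <- micro_origin_profile(map, "GHO", karyotypes = k)
  cls <- setNames(prof$classification, prof$chromosome)
  expect_equal(unname(cls[c("5", "9", "10", "11")]),
               rep("all_micro", 4))
  expect_equal(unname(cls["6"]), "mixed")
  expect_equal(unname(cls["16"]), "insufficient")
  expect_equal(sum(prof$classification == "all_micro"), 4L)

  # unanimity: an all_micro chromosome carries no gene with macrochromosome
  # evidence in any Toxicofera species
  md <- micro_derived_markers(map, karyotypes = k)
  for (ch in prof$chromosome[prof$classification == "all_micro"]) {
    genes <- prof$genes[[which(prof$chromosome == ch)]]
    informative <- genes[genes %in% unique(
      map$locations$symbol[map$locations$species %in%
                             c("VSA", "LRE", "EQU") &
                             map$locations$status == "mapped"])]
    expect_true(all(informative %in% md))
  }
  expect_error(micro_origin_profile(map, "GHO", toxicofera = character(0)),
               "must not be empty")
})

test_that("micro-derived marker calls follow Toxicofera unanimity", {
  map <- .fx("map"); k <- .fx("karyotypes")
  md <- micro_derived_markers(map, karyotypes = k)
  expect_true(all(c("TMEM57", "ACTN4", "HSPA8", "BRD7") %in% md))
  expect_false("EEF2" %in% md)    # macro placement in the snake
  expect_false("TRIM37" %in% md)  # macro placement in the snake
})

test_that("micro-derived marker partitions differ between the two lineages", {
  map <- .fx("map"); k <- .fx("karyotypes")
  ov <- lineage_partition_overlap(map, "GHO", "LAG", karyotypes = k)
  expect_false(ov$partitions_identical)
  # the lacertid chromosome 6 block splits over two gecko chromosomes
  lag6 <- ov$blocks_b[["6"]]
  gho_of <- map$locations[map$locations$species == "GHO" &
                            map$locations$symbol %in% lag6, ]
  expect_setequal(unique(gho_of$chromosome), c("5", "9"))

  self <- lineage_partition_overlap(map, "GHO", "GHO", karyotypes = k)
  expect_true(self$partitions_identical)
  expect_error(lineage_partition_overlap(map, "ACA", "GHO",
                                         toxicofera = "EQU",
                                         karyotypes = k),
               "no shared")
})

test_that("shared ancestral fusions give identical partitions, independent ones do not", {
  tr <- species_tree("((S1:1,(S2:1,S3:1)N23:1)IN:1,OUT:2)R;",
                     outgroup = "OUT")
  shared <- sim_config(
    n_macro = 4, n_micro = 3, markers_per_macro = 2, markers_per_micro = 2,
    branch_events = list(
      N23 = list(list(kind = "tandem_fusion", operands = c("M1", "A1")),
                 list(kind = "tandem_fusion", operands = c("M2", "A2")))),
    seed = 5)
  sim <- sim_evolve(shared, tr)
  ov <- lineage_partition_overlap(sim$map, "S2", "S3", toxicofera = "OUT")
  expect_true(ov$partitions_identical)

  indep <- sim_config(
    n_macro = 4, n_micro = 3, markers_per_macro = 2, markers_per_micro = 2,
    branch_events = list(
      S2 = list(list(kind = "tandem_fusion", operands = c("M1", "A1")),
                list(kind = "tandem_fusion", operands = c("M2", "A2"))),
      S3 = list(list(kind = "tandem_fusion", operands = c("M1", "A2")),
                list(kind = "tandem_fusion", operands = c("M2", "A1")))),
    seed = 5)
  sim2 <- sim_evolve(indep, tr)
  ov2 <- lineage_partition_overlap(sim2$map, "S2", "S3", toxicofera = "OUT")
  expect_false(ov2$partitions_identical)
})
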