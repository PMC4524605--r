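test_that("the same seed reproduces the simulation exactly", {
  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 6, n_micro = 4, markers_per_macro = 3,
                    markers_per_micro = 2,
                    branch_events = list(
                      S2 = list(list(kind = "centric_fusion")),
                      N34 = list(list(kind = "tandem_fusion"),
                                 list(kind = "inversion"))),
                    seed = 31)
  a <- sim_evolve(cfg, tr)
  b <- sim_evolve(cfg, tr)
  expect_true(map_equal(a$map, b$map))
  expect_identical(a$history$applied, b$history$applied)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("with no events every tip matches the ancestral placement", {
  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 5, n_micro = 3, markers_per_macro = 2,
                    markers_per_micro = 2, seed = 12)
  sim <- sim_evolve(cfg, tr)
  loc <- sim$map$locations
  for (sp in setdiff(tree_tips(tr), "OUT")) {
    a <- loc[loc$species == sp, c("symbol", "chromosome", "arm", "is_micro")]
    b <- loc[loc$species == "OUT", c("symbol", "chromosome", "arm",
                                     "is_micro")]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
  ov <- lineage_partition_overlap(sim$map, "S1", "S3", filter = "all")
  expect_true(ov$partitions_identical)
})

test_that("markers are conserved and histories replay exactly", {
  tr <- sim_tree5()
  for (seed in c(4, 5)) {
    set.seed(seed)
    bev <- list(S2 = list(list(kind = "centric_fusion"),
                          list(kind = "inversion")),
                S3 = list(list(kind = "tandem_fusion")),
                N34 = list(list(kind = "centric_fusion")))
    cfg <- sim_config(n_macro = 8, n_micro = 5, markers_per_macro = 3,
                      markers_per_micro = 2, branch_events = bev,
                      seed = seed)
    sim <- sim_evolve(cfg, tr)
    n_markers <- nrow(sim$map$markers)
    for (sp in tree_tips(tr)) {
      rows <- sim$map$locations[sim$map$locations$species == sp, ]
      expect_equal(nrow(rows), n_markers)
      expect_false(anyDuplicated(rows$symbol) > 0)
      expect_true(all(rows$status == "mapped"))
    }
    expect_true(sim_replay(sim$history))
  }
})

test_that("the chromosome census follows the event arithmetic", {
  tr <- sim_tree5()
  cfg0 <- sim_config(n_macro = 19, n_micro = 12, markers_per_macro = 1,
                     markers_per_micro = 1, seed = 1)
  sim0 <- sim_evolve(cfg0, tr)
  c0 <- chromosome_census(sim0$history, "S1")
  expect_equal(c0$chromosome_count, 31L)
  expect_equal(c0$micro_count, 12L)
  expect_error(chromosome_census(sim0$history, "nope"), "unknown tip")

  # k fusions and j fissions: count = ancestral - k + j (here k = 3 centric
  # fusions and one tandem fusion, j = 1); the tandem fusion and the
  # micro-micro centric fusion each remove one microchromosome
  cfg <- sim_config(
    n_macro = 19, n_micro = 12, markers_per_macro = 1,
    markers_per_micro = 1,
    branch_events = list(
      S2 = list(list(kind = "centric_fusion", operands = c("A1", "A2")),
                list(kind = "centric_fusion", operands = c("A3", "A4")),
                list(kind = "centric_fission", operands = "A1A2"),
                list(kind = "tandem_fusion", operands = c("M1", "A5")),
                list(kind = "centric_fusion", operands = c("M2", "M3")))),
    seed = 2)
  sim <- sim_evolve(cfg, tr)
  cs <- chromosome_census(sim$history, "S2")
  expect_equal(cs$chromosome_count, 31L - 3L + 1L - 1L)
  expect_equal(cs$micro_count, 12L - 1L - 1L)
})

test_that("invalid simulated events are rejected", {
  tr <- sim_tree5()
  bad1 <- sim_config(n_macro = 3, n_micro = 1, markers_per_macro = 1,
                     markers_per_micro = 1,
                     branch_events = list(
                       S2 = list(list(kind = "centric_fusion",
                                      operands = c("A1", "ZZ")))),
                     seed = 1)
  expect_error(sim_evolve(bad1, tr), "nonexistent")

  bad2 <- sim_config(n_macro = 3, n_micro = 1, markers_per_macro = 1,
                     markers_per_micro = 1,
                     branch_events = list(
                       S2 = list(list(kind = "centric_fusion",
                                      operands = c("A1", "A2")),
                                 list(kind = "centric_fusion",
                                      operands = c("A1A2", "A3")))),
                     seed = 1)
  expect_error(sim_evolve(bad2, tr), "one-armed")
})

test_that("a tip-branch fusion is recovered with kind, operands and branch", {
  sc <- recovery_replicate(99)
  expect_gte(sc$n_true, 4L)
  expect_gte(sc$rate, 0.75)

  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 6, n_micro = 0, markers_per_macro = 3,
                    markers_per_micro = 0,
                    branch_events = list(
                      S4 = list(list(kind = "centric_fusion",
                                     operands = c("A2", "A5")))),
                    seed = 77)
  sim <- sim_evolve(cfg, tr)
  ev <- infer_scenario(sim$map, sim$karyotypes, sim$landmarks, tr,
                       config = list(exclude = character(0),
                                     toxicofera = "S1",
                                     detect_species = character(0)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "centric_fusion")
  expect_equal(ev$branch, "S4")
  expect_setequal(ev$operands[[1]], c("proto-S1A2", "proto-S1A5"))
})
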