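get_class <- function(classes, sp, chrom) {
  for (c0 in classes) {
    if (c0$species == sp && c0$chromosome == chrom) return(c0)
  }
  NULL
}

test_that("arm-level correspondences recover the published arm homologies", {
  map <- .fx("map"); k <- .fx("karyotypes")
  cl <- classify_correspondence(segment_table(map, "GHO", "LRE"), k)

  lre4 <- get_class(cl, "LRE", "4")
  expect_equal(lre4$pattern, "arms_to_two_wholes")
  expect_equal(lre4$arm_detail$p$chrom, "6")
  expect_equal(lre4$arm_detail$q$chrom, "3")

  lre6 <- get_class(cl, "LRE", "6")
  expect_equal(lre6$arm_detail$p$chrom, "12")
  expect_equal(lre6$arm_detail$q$chrom, "8")
})

test_that("identical single-chromosome maps classify one-to-one", {
  tr <- species_tree("((S1:1,S2:1)IN:1,OUT:2)R;", outgroup = "OUT")
  cfg <- sim_config(n_macro = 1, n_micro = 0, markers_per_macro = 4,
                    markers_per_micro = 0, seed = 3)
  sim <- sim_evolve(cfg, tr)
  cl <- classify_correspondence(segment_table(sim$map, "S1", "S2"),
                                sim$karyotypes)
  expect_true(all(vapply(cl, function(c0) c0$pattern, "") ==
                    "one_to_one_whole"))
})

test_that("centric fusions are polarized onto the correct branches", {
  map <- .fx("map"); k <- .fx("karyotypes"); tr <- .fx("tree")

  cl <- classify_correspondence(segment_table(map, "GHO", "LRE"), k)
  lre3 <- get_class(cl, "LRE", "3")
  ev <- polarize_fusion_fission(lre3, tr, k, map)
  expect_equal(ev$kind, "centric_fusion")
  expect_equal(ev$branch, "Toxicofera")
  expect_setequal(ev$operands[[1]], c("proto-GHO13", "proto-GHO15"))
  expect_equal(ev$confidence, "polarized")

  cl2 <- classify_correspondence(segment_table(map, "GHO", "LAG"), k)
  gho1 <- get_class(cl2, "GHO", "1")
  ev2 <- polarize_fusion_fission(gho1, tr, k, map)
  expect_equal(ev2$kind, "centric_fusion")
  expect_equal(ev2$branch, "Gekkota")

  expect_error(polarize_fusion_fission(get_class(cl, "GHO", "7"), tr, k,
                                       map),
               "arms_to_two_wholes")
})

test_that("a fusion between sister tips without outgroup data is ambiguous", {
  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 6, n_micro = 0, markers_per_macro = 3,
                    markers_per_micro = 0,
                    branch_events = list(
                      S3 = list(list(kind = "centric_fusion",
                                     operands = c("A1", "A2")))),
                    seed = 9)
  sim <- sim_evolve(cfg, tr)
  # keep only the sister pair in the map; the outgroup has no data
  f <- withr::local_tempfile(fileext = ".tsv")
  write_comparative_map(sim$map, f)
  pair_map <- read_comparative_map(f, species = c("S3", "S4"))
  corr <- Filter(function(c0) c0$pattern == "arms_to_two_wholes",
                 classify_correspondence(segment_table(pair_map, "S4", "S3"),
                                         sim$karyotypes))[[1]]
  ev <- polarize_fusion_fission(corr, tr, sim$karyotypes, pair_map)
  expect_equal(ev$confidence, "ambiguous")
  expect_true(is.na(ev$branch))
  expect_match(ev$note, "centric_fission")
})

test_that("rerooting flips a polarized fusion into the dual fission", {
  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 8, n_micro = 0, markers_per_macro = 3,
                    markers_per_micro = 0,
                    branch_events = list(
                      S3 = list(list(kind = "centric_fusion",
                                     operands = c("A1", "A2")))),
                    seed = 7)
  sim <- sim_evolve(cfg, tr)
  corr <- Filter(function(c0) c0$pattern == "arms_to_two_wholes",
                 classify_correspondence(segment_table(sim$map, "S1", "S3"),
                                         sim$karyotypes))[[1]]
  e1 <- polarize_fusion_fission(corr, tr, sim$karyotypes, sim$map)
  e2 <- polarize_fusion_fission(corr, reroot_tree(tr, "S3"),
                                sim$karyotypes, sim$map)
  expect_equal(e1$kind, "centric_fusion")
  expect_equal(e2$kind, "centric_fission")
  expect_false(is.na(e2$branch))
  expect_identical(e1$operands, e2$operands)
  expect_identical(e1$evidence, e2$evidence)
})

test_that("ITS and micro-origin evidence yield tandem and micro fusions", {
  map <- .fx("map"); k <- .fx("karyotypes"); lm <- .fx("landmarks")
  tr <- .fx("tree")
  prof <- micro_origin_profile(map, "GHO", karyotypes = k)
  ev <- detect_tandem_fusion(lm, prof, map, "GHO", karyotypes = k,
                             tree = tr)
  tand <- ev[ev$kind == "tandem_fusion", ]
  expect_equal(tand$product, "GHO14")
  expect_setequal(tand$operands[[1]], c("GHO14p", "proto-GHO14q"))

  mf <- ev[ev$kind == "micro_fusion", ]
  expect_setequal(mf$product, c("GHO5", "GHO9", "GHO10"))

  no_its <- lm[lm$kind != "ITS", ]
  ev2 <- detect_tandem_fusion(no_its, prof, map, "GHO", karyotypes = k,
                              tree = tr)
  expect_false(any(ev2$kind == "tandem_fusion"))
})

test_that("scenario inference emits the full named fusion scenario", {
  ev <- .fx("events")
  products <- function(kind, branch) {
    unique(unlist(ev$products[ev$kind == kind & !is.na(ev$branch) &
                                ev$branch == branch]))
  }
  tox <- products("centric_fusion", "Toxicofera")
  expect_true(all(c("LRE2", "LRE3", "LRE4", "LRE5", "LRE6") %in% tox))
  gek <- products("centric_fusion", "Gekkota")
  expect_true(all(c("GHO1", "GHO2") %in% gek))
  expect_true("GHO14" %in% products("tandem_fusion", "Gekkota"))
  expect_true("LAG6" %in% products("micro_fusion", "Lacertidae"))

  # LRE5 joins the gecko 7 with the long arm of the tandem-fusion product 14
  i <- which(vapply(ev$products, function(p) "LRE5" %in% p, logical(1)))
  expect_setequal(ev$operands[[i]], c("proto-GHO7", "proto-GHO14q"))
})

test_that("scenario inference is deterministic and errors usefully", {
  map <- .fx("map"); k <- .fx("karyotypes"); lm <- .fx("landmarks")
  tr <- .fx("tree")
  e1 <- .fx("events")
  e2 <- infer_scenario(map, k, lm, tr)
  expect_identical(e1, e2)

  expect_error(infer_scenario(map, k, lm, tr,
                              config = list(pairs = list(c("GHO", "XXX")))),
               "XXX")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_comparative_map(map, f)
  solo <- read_comparative_map(f, species = "GHO")
  ev0 <- infer_scenario(solo, k, lm, tr)
  expect_equal(nrow(ev0), 0L)
})

test_that("marker-order inversion flags are qualitative and unpolarized", {
  map <- .fx("map")
  fl <- flag_inversions(map, "GHO", "LRE")
  if (nrow(fl)) {
    expect_true(all(fl$kind == "paracentric_inversion"))
    expect_true(all(fl$confidence == "ambiguous"))
    expect_true(all(is.na(fl$branch)))
    expect_match(fl$note[1], "row_order")
  }
  succeed()
})
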