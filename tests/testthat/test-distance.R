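test_that("breakpoint counting treats orientation and ends as free", {
  expect_equal(breakpoint_count(1:5, 1:5), 0L)
  expect_equal(breakpoint_count(1:3, 3:1), 0L)
  expect_equal(breakpoint_count(c(1, 3, 2, 4), 1:4), 2L)
  expect_equal(breakpoint_count("a", "a"), 0L)
  expect_error(breakpoint_count(1:3, 1:4), "same marker set")
  expect_error(breakpoint_count(c(1, 2), c(1, 3)), "same marker set")
})

test_that("the reversal-distance oracle is exact on canonical cases", {
  expect_equal(reversal_distance_exact(1:6), 0L)
  expect_equal(reversal_distance_exact(c(2, 1, 3, 4)), 1L)
  expect_equal(reversal_distance_exact(c(3, 1, 2)), 2L)
  expect_error(reversal_distance_exact(1:9), "n <= 8")
  expect_error(reversal_distance_exact(c(1, 1, 2)), "permutation")
  # character orders need a reference
  expect_equal(reversal_distance_exact(c("b", "a", "c"),
                                       reference = c("a", "b", "c")), 1L)
})

test_that("random n=6 permutations respect the breakpoint and length bounds", {
  set.seed(21)
  for (i in 1:50) {
    p <- sample(6)
    d <- reversal_distance_exact(p)
    b <- breakpoint_count(p, 1:6)
    expect_gte(d, ceiling(b / 2))
    expect_lte(d, 5L)
  }
})

test_that("marker orders carry their provenance", {
  map <- .fx("map")
  o <- marker_order(map, "GHO", "1", arm = "p")
  expect_equal(o, structure(c("XAB1", "FBXW11", "ESR1"),
                            provenance = "row_order"),
               ignore_attr = FALSE)

  tr <- species_tree("((S1:1,S2:1)IN:1,OUT:2)R;", outgroup = "OUT")
  cfg <- sim_config(n_macro = 2, n_micro = 0, markers_per_macro = 4,
                    markers_per_micro = 0, seed = 2)
  sim <- sim_evolve(cfg, tr)
  os <- marker_order(sim$map, "S1", "A1")
  expect_equal(attr(os, "provenance"), "explicit_rank")
  expect_equal(length(os), 4L)
})
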