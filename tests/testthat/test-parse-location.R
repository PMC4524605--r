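test_that("location dialect tokens parse to the documented fields", {
  loc <- parse_location("2q12.2 –q21.1", "LRE")
  expect_equal(loc$chromosome, "2")
  expect_equal(loc$arm, "q")
  expect_equal(loc$band_start, "12.2")
  expect_equal(loc$band_end, "21.1")
  expect_equal(loc$status, "mapped")

  grp <- parse_location("11–18", "LAG")
  expect_true(grp$is_micro_group)
  expect_false(grp$is_micro)
  expect_equal(grp$status, "mapped")

  expect_equal(parse_location("", "GHO")$status, "missing")
  expect_equal(parse_location("–", "ACA")$status, "missing")
  expect_equal(parse_location("un", "ACA")$status, "unknown")

  sex <- parse_location("4 (ZW)", "GHO")
  expect_equal(sex$chromosome, "4")
  expect_equal(sex$sex_annotation, "ZW")
  expect_equal(sex$arm, "whole")

  mic <- parse_location("Micro", "VSA")
  expect_true(mic$is_micro)
  expect_false(mic$is_micro_group)

  za <- parse_location("Zq", "GGA")
  expect_equal(za$chromosome, "Z")
  expect_equal(za$arm, "q")
})

test_that("a centromere-spanning interval keeps arm-qualified bands", {
  loc <- parse_location("3p11.1 –q11", "LRE")
  expect_equal(loc$chromosome, "3")
  expect_equal(loc$arm, "whole")
  expect_equal(loc$band_start, "p11.1")
  expect_equal(loc$band_end, "q11")
})

test_that("unparseable cells raise an error naming the token", {
  expect_error(parse_location("?!*", "GHO"), "cannot parse")
  expect_error(parse_location("12q3-", "GHO"), "cannot parse")
})

test_that("every fixture cell parses and survives a format round-trip", {
  map <- .fx("map")
  expect_equal(nrow(map$locations), 86L * 7L)
  expect_true(all(map$locations$status %in%
                    c("mapped", "unknown", "missing")))
  for (i in seq_len(nrow(map$locations))) {
    row <- map$locations[i, ]
    loc <- .get_location_row(row)
    back <- parse_location(format_location(loc), row$species)
    for (f in c("chromosome", "arm", "band_start", "band_end", "is_micro",
                "is_micro_group", "sex_annotation", "status")) {
      expect_identical(back[[f]], loc[[f]],
                       info = paste(row$symbol, row$species, row$raw, f))
    }
  }
})
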