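#' Recompute the headline comparative-map results and check them
#'
#' Runs the full pipeline on a fixture bundle (by default the packaged
#' comparative map, karyotypes, landmarks and species tree) and compares the
#' recomputed quantities — marker tallies, the conserved-macrochromosome
#' set, the avian units represented, the micro-composed chromosome set,
#' per-chromosome gene counts and the named fusion events — against the
#' expected values shipped in a versioned YAML file.
#'
#' @param map,karyotypes,landmarks,tree Fixture bundle; defaults to the
#'   packaged tables.
#' @param expected Path to the expected-values YAML (default: packaged
#'   `expected_checks.yaml`).
#' @param focal Focal species (default `"GHO"`).
#' @param lacertid Lacertid comparison species (default `"LAG"`).
#' @return A `reproduction_report`: a list with per-check entries
#'   (`computed`, `expected`, `pass`) and an overall `pass` flag.
#' @export
run_reproduction <- function(map = gecko_map(),
                             karyotypes = gecko_karyotypes(),
                             landmarks = gecko_landmarks(),
                             tree = gecko_tree(),
                             expected = NULL,
                             focal = "GHO", lacertid = "LAG") {
  if (is.null(expected)) expected <- .extdata("expected_checks.yaml")
  exp <- yaml::read_yaml(expected)
  checks <- list()
  add <- function(name, computed, want) {
    checks[[name]] <<- list(computed = computed, expected = want,
                            pass = isTRUE(all.equal(computed, want)))
  }
  add_set <- function(name, computed, want) {
    checks[[name]] <<- list(computed = computed, expected = want,
                            pass = setequal(computed, want))
  }

  add("total_markers", nrow(map$markers), exp$total_markers)
  add("newly_mapped", sum(!map$markers$previously_mapped), exp$newly_mapped)
  add("previously_mapped", sum(map$markers$previously_mapped),
      exp$previously_mapped)
  add("probes_cloned_from_gecko",
      sum(map$markers$origin == focal & !map$markers$previously_mapped),
      exp$probes_cloned_from_gecko)
  tal <- as.list(table(map$markers$origin))
  for (sp in names(exp$origin_tallies)) {
    add(paste0("origin_", sp), as.integer(tal[[sp]] %||% 0L),
        exp$origin_tallies[[sp]])
  }

  cons <- conserved_macro_chromosomes(map, focal)
  add_set("conserved_macro_chromosomes", cons,
          as.character(exp$conserved_macro_chromosomes))
  add_set("avian_units_hit", hit_units(map, focal),
          as.character(exp$avian_units_hit))
  add_set("lacertid_macro_chromosomes",
          conserved_macro_chromosomes(map, lacertid),
          as.character(exp$lacertid_macro_chromosomes))

  counts <- table(map$locations$chromosome[
    map$locations$species == focal & map$locations$status == "mapped" &
      !map$locations$is_micro & !map$locations$is_micro_group])
  for (ch in names(exp$gene_counts)) {
    add(paste0("genes_on_", focal, ch), as.integer(counts[[ch]] %||% 0L),
        exp$gene_counts[[ch]])
  }
  if (isTRUE(exp$gho7_all_on_gga4q)) {
    g7 <- map$locations$symbol[map$locations$species == focal &
                                 map$locations$status == "mapped" &
                                 map$locations$chromosome == "7"]
    gga <- map$locations[map$locations$species == "GGA" &
                           map$locations$symbol %in% g7, ]
    add("gho7_all_on_gga4q",
        all(gga$chromosome == "4" & gga$arm == "q"), TRUE)
  }

  prof <- micro_origin_profile(map, focal, karyotypes = karyotypes)
  add_set("micro_composed",
          prof$chromosome[prof$classification == "all_micro"],
          as.character(exp$micro_composed))

  part <- lineage_partition_overlap(map, focal, lacertid,
                                    karyotypes = karyotypes)
  add("partitions_identical_with_lacertid", part$partitions_identical,
      exp$partitions_identical_with_lacertid)

  events <- infer_scenario(map, karyotypes, landmarks, tree)
  fus <- events[events$kind == "centric_fusion" &
                  events$confidence == "polarized", , drop = FALSE]
  for (br in names(exp$fusion_products)) {
    want <- as.character(exp$fusion_products[[br]])
    got <- unique(unlist(fus$products[fus$branch == br]))
    add(paste0("fusions_", br), all(want %in% got), TRUE)
  }
  tand <- events[events$kind == "tandem_fusion", , drop = FALSE]
  add("tandem_fusions",
      all(as.character(exp$tandem_fusion_products) %in%
            unlist(tand$products)), TRUE)

  structure(list(checks = checks,
                 pass = all(vapply(checks, `[[`, logical(1), "pass")),
                 events = events),
            class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction report:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    fmt <- function(v) paste(format(v, trim = TRUE), collapse = ",")
    cat(sprintf("  [%s] %-38s computed=%s expected=%s\n",
                if (ck$pass) "ok" else "XX", nm, fmt(ck$computed),
                fmt(ck$expected)))
  }
  invisible(x)
}

#' Serialise a reproduction report to stable JSON
#'
#' @param report A `reproduction_report`.
#' @return A JSON string (stable key order and formatting across runs).
#' @export
report_json <- function(report) {
  body <- lapply(report$checks, function(ck) {
    list(computed = ck$computed, expected = ck$expected, pass = ck$pass)
  })
  jsonlite::toJSON(list(pass = report$pass, checks = body),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
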