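# memoised fixture bundle (parsing the packaged map once per test run)
.fx <- local({
  cache <- new.env()
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <- switch(name,
                              map = gecko_map(),
                              karyotypes = gecko_karyotypes(),
                              landmarks = gecko_landmarks(),
                              tree = gecko_tree(),
                              events = infer_scenario(.fx("map"),
                                                      .fx("karyotypes"),
                                                      .fx("landmarks"),
                                                      .fx("tree")))
    }
    cache[[name]]
  }
})

# five-tip study-shaped simulation tree: one outgroup, one basal ingroup tip,
# one intermediate tip and a terminal cherry, with labelled internal nodes
sim_tree5 <- function() {
  species_tree("((S1:1,(S2:1,(S3:1,S4:1)N34:1)N234:1)IN:1,OUT:2)R;",
               outgroup = "OUT")
}

# one recovery replicate: 1-3 random centric fusions on each derived branch,
# three markers per ancestral macrochromosome
recovery_replicate <- function(seed) {
  set.seed(seed)
  branches <- c("S2", "S3", "S4", "N34")
  bev <- lapply(branches, function(b) {
    replicate(sample(1:3, 1), list(kind = "centric_fusion"),
              simplify = FALSE)
  })
  names(bev) <- branches
  tr <- sim_tree5()
  cfg <- sim_config(n_macro = 19, n_micro = 6, markers_per_macro = 3,
                    markers_per_micro = 2, branch_events = bev, seed = seed)
  sim <- sim_evolve(cfg, tr)
  ev <- infer_scenario(sim$map, sim$karyotypes, sim$landmarks, tr,
                       config = list(exclude = character(0),
                                     toxicofera = "S1",
                                     detect_species = character(0)))
  score_fusion_recovery(sim$history, ev)
}

# one row of a locations table as a chrom_location object
.get_location_row <- function(row) {
  loc <- as.list(row[c("chromosome", "arm", "band_start", "band_end",
                       "is_micro", "is_micro_group", "sex_annotation",
                       "status")])
  loc$species <- row$species
  class(loc) <- "chrom_location"
  loc
}

# write a small comparative-map TSV and read it back
read_map_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f, useBytes = TRUE)
  read_comparative_map(f)
}
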