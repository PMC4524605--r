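#' Default avian macrochromosome unit set
#'
#' The chicken macrochromosomes and macrochromosome arms against which
#' squamate chromosomes are scored for conserved macrochromosome content:
#' GGA1p, 1q, 2p, 2q, 3, 4q, 5, 6, 7, 8 and Z.  GGA4p is deliberately not a
#' member (it behaves as a fused ancestral microchromosome), and the set is
#' fully configurable wherever it is consumed.
#'
#' @return Character vector of unit tokens.
#' @export
avian_macro_units <- function() {
  c("1p", "1q", "2p", "2q", "3", "4q", "5", "6", "7", "8", "Z")
}

# natural sort for chromosome labels: numeric labels first in numeric order,
# then alphanumeric labels
.label_sort <- function(x) {
  x <- unique(x)
  num <- suppressWarnings(as.numeric(x))
  c(x[!is.na(num)][order(num[!is.na(num)])], sort(x[is.na(num)]))
}

# (chromosome, arm) side token for segment aggregation; unidentified
# microchromosomes collapse to the "Micro" pseudo-label, micro-group ranges
# keep their range label
.side_chrom <- function(rows) {
  ifelse(rows$is_micro, "Micro", rows$chromosome)
}
.side_arm <- function(rows) {
  ifelse(rows$is_micro | rows$is_micro_group, "whole", rows$arm)
}

#' Pairwise conserved synteny segments
#'
#' A synteny segment links a chromosome (or chromosome arm) of one species to
#' a chromosome/arm of another through the set of gene markers co-located on
#' both: one row per distinct (side A, side B) pair sharing at least one
#' marker mapped in both species.  Markers on unidentified microchromosomes
#' aggregate into a single `"Micro"` side; micro-group range labels form their
#' own side.  Rows are ordered by decreasing support and then lexically.
#'
#' @param map A `comparative_map`.
#' @param sp_a,sp_b Distinct species tokens from the map roster.
#' @return A data.frame of class `segment_table` with columns `chrom_a`,
#'   `arm_a`, `chrom_b`, `arm_b`, `support_count` and the list column
#'   `support` (marker symbols).
#' @export
segment_table <- function(map, sp_a, sp_b) {
  stopifnot(inherits(map, "comparative_map"))
  if (identical(sp_a, sp_b)) {
    stop("sp_a and sp_b must be different species", call. = FALSE)
  }
  for (sp in c(sp_a, sp_b)) {
    if (!sp %in% map$species) stop("species ", sp, " not in map roster",
                                   call. = FALSE)
  }
  la <- map$locations[map$locations$species == sp_a &
                        map$locations$status == "mapped", ]
  lb <- map$locations[map$locations$species == sp_b &
                        map$locations$status == "mapped", ]
  shared <- intersect(la$symbol, lb$symbol)
  empty <- data.frame(chrom_a = character(), arm_a = character(),
                      chrom_b = character(), arm_b = character(),
                      support_count = integer(), stringsAsFactors = FALSE)
  empty$support <- list()
  if (!length(shared)) {
    return(structure(empty, class = c("segment_table", "data.frame"),
                     sp_a = sp_a, sp_b = sp_b))
  }
  la <- la[match(shared, la$symbol), ]
  lb <- lb[match(shared, lb$symbol), ]
  key <- paste(.side_chrom(la), .side_arm(la),
               .side_chrom(lb), .side_arm(lb), sep = "\r")
  groups <- split(shared, key)
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  seg <- data.frame(chrom_a = vapply(parts, `[`, "", 1),
                    arm_a = vapply(parts, `[`, "", 2),
                    chrom_b = vapply(parts, `[`, "", 3),
                    arm_b = vapply(parts, `[`, "", 4),
                    support_count = lengths(groups),
                    stringsAsFactors = FALSE)
  seg$support <- unname(groups)
  ord <- order(-seg$support_count, seg$chrom_a, seg$arm_a, seg$chrom_b,
               seg$arm_b)
  seg <- seg[ord, ]
  rownames(seg) <- NULL
  structure(seg, class = c("segment_table", "data.frame"),
            sp_a = sp_a, sp_b = sp_b)
}

#' @export
print.segment_table <- function(x, ...) {
  cat("Synteny segments:", attr(x, "sp_a"), "vs", attr(x, "sp_b"),
      "(", nrow(x), "segments,", sum(x$support_count), "shared markers )\n")
  df <- as.data.frame(x)
  df$support <- vapply(df$support, paste, "", collapse = ",")
  print(df, ...)
  invisible(x)
}

# unit tokens matched by one chicken location: an arm-level location matches
# both its arm unit and the whole-chromosome unit; a chromosome-level
# location matches only the whole-chromosome unit
.unit_hits <- function(chromosome, arm, is_micro, is_micro_group, units) {
  if (is.na(chromosome) || is_micro || is_micro_group) return(character(0))
  cand <- if (arm %in% c("p", "q")) c(paste0(chromosome, arm), chromosome)
          else chromosome
  intersect(cand, units)
}

#' Chromosomes with conserved avian macrochromosome content
#'
#' Returns the chromosomes of `species` that carry at least one gene whose
#' chicken location falls inside the avian macrochromosome unit set.  A gene
#' recorded on a chicken arm (e.g. `2p`) matches both the arm unit `2p` and a
#' whole-chromosome unit `2`; a gene recorded without an arm matches only the
#' whole-chromosome unit.  Unidentified microchromosome and micro-group
#' pseudo-labels are never reported as conserved chromosomes.
#'
#' @param map A `comparative_map`.
#' @param species Species whose chromosomes are scored.
#' @param units Character vector of chicken unit tokens
#'   (default [avian_macro_units()]).
#' @param chicken Chicken species token in the roster (default `"GGA"`).
#' @return Sorted character vector of chromosome labels.
#' @export
conserved_macro_chromosomes <- function(map, species,
                                        units = avian_macro_units(),
                                        chicken = "GGA") {
  stopifnot(inherits(map, "comparative_map"))
  if (!chicken %in% map$species) {
    stop("chicken token ", chicken, " not in map roster", call. = FALSE)
  }
  ls <- map$locations[map$locations$species == species &
                        map$locations$status == "mapped", ]
  lg <- map$locations[map$locations$species == chicken &
                        map$locations$status == "mapped", ]
  shared <- intersect(ls$symbol, lg$symbol)
  out <- character(0)
  for (sym in shared) {
    a <- ls[ls$symbol == sym, ][1, ]
    g <- lg[lg$symbol == sym, ][1, ]
    if (a$is_micro || a$is_micro_group) next
    hits <- .unit_hits(g$chromosome, g$arm, g$is_micro, g$is_micro_group,
                       units)
    if (length(hits)) out <- c(out, a$chromosome)
  }
  .label_sort(out)
}

#' Avian units represented on a species' conserved chromosomes
#'
#' The subset of `units` carrying at least one gene that maps to any
#' chromosome returned by [conserved_macro_chromosomes()] for the same unit
#' set.
#'
#' @inheritParams conserved_macro_chromosomes
#' @return Sorted character vector of unit tokens.
#' @export
hit_units <- function(map, species, units = avian_macro_units(),
                      chicken = "GGA") {
  chroms <- conserved_macro_chromosomes(map, species, units, chicken)
  if (!length(chroms)) return(character(0))
  ls <- map$locations[map$locations$species == species &
                        map$locations$status == "mapped", ]
  lg <- map$locations[map$locations$species == chicken &
                        map$locations$status == "mapped", ]
  shared <- intersect(ls$symbol, lg$symbol)
  out <- character(0)
  for (sym in shared) {
    a <- ls[ls$symbol == sym, ][1, ]
    if (a$is_micro || a$is_micro_group || !(a$chromosome %in% chroms)) next
    g <- lg[lg$symbol == sym, ][1, ]
    out <- c(out, .unit_hits(g$chromosome, g$arm, g$is_micro,
                             g$is_micro_group, units))
  }
  .label_sort(out)
}

# per-(marker, toxicofera species) micro/macro evidence
# "micro": located on a (possibly unidentified) microchromosome there
# "macro": located on an identified chromosome of macro size class
.tox_evidence <- function(map, toxicofera, karyotypes = NULL) {
  rows <- map$locations[map$locations$species %in% toxicofera &
                          map$locations$status == "mapped", ]
  if (!nrow(rows)) {
    return(data.frame(symbol = character(), species = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  ev <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    if (rows$is_micro[i] || rows$is_micro_group[i]) {
      ev[i] <- "micro"
    } else {
      sc <- .size_class(karyotypes, rows$species[i], rows$chromosome[i])
      ev[i] <- if (identical(sc, "micro")) "micro" else "macro"
    }
  }
  data.frame(symbol = rows$symbol, species = rows$species, evidence = ev,
             stringsAsFactors = FALSE)
}

#' Markers of microchromosomal origin
#'
#' A marker counts as micro-derived when every Toxicofera species with data
#' for it places it on a microchromosome (at least one informative species
#' required).
#'
#' @param map A `comparative_map`.
#' @param toxicofera Species tokens providing the micro/macro evidence.
#' @param karyotypes Optional `karyotype_set` used to resolve the size class
#'   of identified chromosomes; without it, any identified chromosome label
#'   counts as macro.
#' @return Character vector of marker symbols.
#' @export
micro_derived_markers <- function(map, toxicofera = c("VSA", "LRE", "EQU"),
                                  karyotypes = NULL) {
  ev <- .tox_evidence(map, toxicofera, karyotypes)
  syms <- unique(ev$symbol)
  syms[vapply(syms, function(s) all(ev$evidence[ev$symbol == s] == "micro"),
              logical(1))]
}

#' Microchromosome-origin profile of a species' chromosomes
#'
#' For every chromosome of `species` carrying at least one informative gene
#' (a gene with micro/macro evidence in the Toxicofera reference species),
#' classifies the chromosome as:
#' \describe{
#'   \item{all_micro}{at least two informative genes, each located on a
#'     microchromosome in every Toxicofera species with data for it — the
#'     signature of a chromosome assembled from ancestral microchromosomes;}
#'   \item{mixed}{at least one micro and one macro evidence instance — a
#'     macrochromosome that acquired microchromosome segments;}
#'   \item{all_macro}{only macro evidence;}
#'   \item{insufficient}{fewer than two informative genes.}
#' }
#' `segment_count` is the number of distinct chicken chromosome/arm segments
#' represented among the chromosome's genes.
#'
#' @inheritParams micro_derived_markers
#' @param species Species whose chromosomes are profiled.
#' @param chicken Chicken token for segment counting (default `"GGA"`).
#' @return A data.frame with columns `chromosome`, `classification`,
#'   `n_informative`, `segment_count` and list column `genes`.
#' @export
micro_origin_profile <- function(map, species,
                                 toxicofera = c("VSA", "LRE", "EQU"),
                                 karyotypes = NULL, chicken = "GGA") {
  if (!length(toxicofera)) {
    stop("toxicofera evidence species list must not be empty", call. = FALSE)
  }
  ev <- .tox_evidence(map, toxicofera, karyotypes)
  ls <- map$locations[map$locations$species == species &
                        map$locations$status == "mapped", ]
  lg <- map$locations[map$locations$species == chicken &
                        map$locations$status == "mapped", ]
  chroms <- .label_sort(.side_chrom(ls))
  res <- lapply(chroms, function(ch) {
    genes <- ls$symbol[.side_chrom(ls) == ch]
    gene_ev <- ev[ev$symbol %in% genes, ]
    informative <- unique(gene_ev$symbol)
    n_inf <- length(informative)
    cls <- if (n_inf < 2L) {
      if (n_inf == 0L) return(NULL) else "insufficient"
    } else {
      unanimity <- vapply(informative, function(s) {
        all(gene_ev$evidence[gene_ev$symbol == s] == "micro")
      }, logical(1))
      if (all(unanimity)) "all_micro"
      else if (any(gene_ev$evidence == "micro") &&
               any(gene_ev$evidence == "macro")) "mixed"
      else "all_macro"
    }
    gg <- lg[lg$symbol %in% genes & !lg$is_micro & !lg$is_micro_group, ]
    segs <- unique(ifelse(gg$arm %in% c("p", "q"),
                          paste0(gg$chromosome, gg$arm), gg$chromosome))
    data.frame(chromosome = ch, classification = cls, n_informative = n_inf,
               segment_count = length(segs), stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chromosome = character(), classification = character(),
               n_informative = integer(), segment_count = integer(),
               stringsAsFactors = FALSE)
  out$genes <- lapply(out$chromosome,
                      function(ch) ls$symbol[.side_chrom(ls) == ch])
  rownames(out) <- NULL
  out
}

#' Compare two lineages' partitions of micro-derived markers
#'
#' Restricted to markers that are micro-derived in the Toxicofera reference
#' species and mapped to an identified chromosome (or micro-group) in both
#' species, partitions the markers into chromosomes per species and reports
#' whether the two partitions coincide block by block.  Identical partitions
#' are the signature of fusions shared by common descent; non-identical
#' partitions indicate lineage-independent fusion histories.
#'
#' @inheritParams micro_derived_markers
#' @param sp_a,sp_b Species to compare.
#' @param filter `"micro_derived"` (default) restricts to markers of
#'   microchromosomal origin; `"all"` uses every marker identified in both
#'   species.
#' @return A list with `partitions_identical`, the named block lists
#'   `blocks_a` and `blocks_b`, and `markers` used.
#' @export
lineage_partition_overlap <- function(map, sp_a, sp_b,
                                      toxicofera = c("VSA", "LRE", "EQU"),
                                      karyotypes = NULL,
                                      filter = c("micro_derived", "all")) {
  filter <- match.arg(filter)
  filt <- if (filter == "micro_derived") {
    micro_derived_markers(map, toxicofera, karyotypes)
  } else {
    map$markers$symbol
  }
  pick <- function(sp) {
    rows <- map$locations[map$locations$species == sp &
                            map$locations$status == "mapped" &
                            map$locations$symbol %in% filt &
                            !map$locations$is_micro, ]
    rows
  }
  ra <- pick(sp_a); rb <- pick(sp_b)
  shared <- intersect(ra$symbol, rb$symbol)
  if (!length(shared)) {
    stop("no shared micro-derived markers between ", sp_a, " and ", sp_b,
         call. = FALSE)
  }
  ra <- ra[ra$symbol %in% shared, ]; rb <- rb[rb$symbol %in% shared, ]
  blocks <- function(rows) {
    sp_blocks <- split(rows$symbol, rows$chromosome)
    lapply(sp_blocks, function(b) sort(unique(b)))
  }
  ba <- blocks(ra); bb <- blocks(rb)
  canon <- function(b) sort(vapply(b, paste, "", collapse = ","))
  list(partitions_identical = identical(canon(ba), canon(bb)),
       blocks_a = ba, blocks_b = bb, markers = sort(shared))
}
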