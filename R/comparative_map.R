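# A comparative_map is a list with
#   species   : character vector of species tokens (column order preserved)
#   markers   : data.frame(symbol, origin, length_bp, accessions,
#                          previously_mapped)
#   locations : long data.frame, one row per marker x species, with the parsed
#               fields of parse_location() plus the raw cell
#   ranks     : optional data.frame(symbol, species, rank) for explicit
#               within-chromosome marker order

.location_fields <- c("chromosome", "arm", "band_start", "band_end",
                      "is_micro", "is_micro_group", "sex_annotation", "status")

.new_comparative_map <- function(species, markers, locations, ranks = NULL) {
  structure(list(species = species, markers = markers,
                 locations = locations, ranks = ranks),
            class = "comparative_map")
}

#' Read a comparative gene-location table
#'
#' The table is tab-separated with one row per gene marker.  Mandatory columns
#' are `symbol` and `origin`; `length_bp`, `accessions` and
#' `previously_mapped` (`yes`/`no`) are kept as marker metadata when present.
#' Columns named `rank_<species>` supply an explicit within-chromosome marker
#' order; every remaining column is taken as a species location column and its
#' cells are parsed with [parse_location()].
#'
#' @param file Path to a UTF-8 TSV file (or a connection).
#' @param species Optional character vector restricting/validating the species
#'   columns; an entry not present in the header is an error.
#' @return A `comparative_map` object.
#' @seealso [write_comparative_map()], [gecko_map()]
#' @export
read_comparative_map <- function(file, species = NULL) {
  tab <- utils::read.delim(file, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  meta_cols <- c("symbol", "origin", "length_bp", "accessions",
                 "previously_mapped")
  if (!all(c("symbol", "origin") %in% names(tab))) {
    stop("comparative map needs 'symbol' and 'origin' columns", call. = FALSE)
  }
  rank_cols <- grep("^rank_", names(tab), value = TRUE)
  sp_cols <- setdiff(names(tab), c(meta_cols, rank_cols))
  if (!is.null(species)) {
    missing_sp <- setdiff(species, sp_cols)
    if (length(missing_sp)) {
      stop("unknown species column(s): ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
    sp_cols <- species
  }
  dup <- tab$symbol[duplicated(tab$symbol)]
  if (length(dup)) {
    stop("duplicate marker symbol(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  markers <- data.frame(
    symbol = tab$symbol,
    origin = tab$origin,
    length_bp = if ("length_bp" %in% names(tab)) tab$length_bp
                else rep(NA_character_, nrow(tab)),
    accessions = if ("accessions" %in% names(tab)) tab$accessions
                 else rep(NA_character_, nrow(tab)),
    previously_mapped = if ("previously_mapped" %in% names(tab)) {
      tolower(tab$previously_mapped) %in% c("yes", "true", "1")
    } else rep(FALSE, nrow(tab)),
    stringsAsFactors = FALSE
  )

  loc_rows <- vector("list", nrow(tab) * length(sp_cols))
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    for (sp in sp_cols) {
      cell <- tab[[sp]][i]
      loc <- .parse_cell(cell)
      if (is.null(loc)) {
        stop("row ", i, " (", tab$symbol[i], "), species ", sp,
             ": cannot parse location cell ", sQuote(cell), call. = FALSE)
      }
      k <- k + 1L
      loc_rows[[k]] <- data.frame(symbol = tab$symbol[i], species = sp,
                                  raw = cell,
                                  chromosome = loc$chromosome, arm = loc$arm,
                                  band_start = loc$band_start,
                                  band_end = loc$band_end,
                                  is_micro = loc$is_micro,
                                  is_micro_group = loc$is_micro_group,
                                  sex_annotation = loc$sex_annotation,
                                  status = loc$status,
                                  stringsAsFactors = FALSE)
    }
  }
  locations <- if (k) do.call(rbind, loc_rows[seq_len(k)]) else
    data.frame(symbol = character(), species = character(), raw = character(),
               chromosome = character(), arm = character(),
               band_start = character(), band_end = character(),
               is_micro = logical(), is_micro_group = logical(),
               sex_annotation = character(), status = character(),
               stringsAsFactors = FALSE)

  ranks <- NULL
  if (length(rank_cols)) {
    rk <- lapply(rank_cols, function(cn) {
      sp <- sub("^rank_", "", cn)
      val <- suppressWarnings(as.numeric(tab[[cn]]))
      keep <- !is.na(val)
      data.frame(symbol = tab$symbol[keep], species = sp, rank = val[keep],
                 stringsAsFactors = FALSE)
    })
    ranks <- do.call(rbind, rk)
  }
  .new_comparative_map(sp_cols, markers, locations, ranks)
}

#' Write a comparative map to a TSV file
#'
#' Locations are serialised with [format_location()]; band intervals and
#' missing cells come out with the canonical en-dash, so
#' `read_comparative_map(write_comparative_map(m))` reproduces `m` field by
#' field.
#'
#' @param map A `comparative_map`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_comparative_map <- function(map, file) {
  stopifnot(inherits(map, "comparative_map"))
  out <- data.frame(symbol = map$markers$symbol,
                    origin = map$markers$origin,
                    length_bp = map$markers$length_bp,
                    accessions = map$markers$accessions,
                    previously_mapped = ifelse(map$markers$previously_mapped,
                                               "yes", "no"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (sp in map$species) {
    cells <- vapply(map$markers$symbol, function(sym) {
      loc <- .get_location(map, sym, sp)
      format_location(loc)
    }, character(1))
    out[[sp]] <- cells
  }
  if (!is.null(map$ranks)) {
    for (sp in unique(map$ranks$species)) {
      rk <- map$ranks[map$ranks$species == sp, ]
      col <- rep("", nrow(out))
      col[match(rk$symbol, out$symbol)] <- as.character(rk$rank)
      out[[paste0("rank_", sp)]] <- col
    }
  }
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# single-location accessor (as a chrom_location-like list)
.get_location <- function(map, symbol, species) {
  i <- which(map$locations$symbol == symbol & map$locations$species == species)
  if (!length(i)) return(.blank_location("missing"))
  row <- map$locations[i[1], ]
  loc <- as.list(row[c("chromosome", "arm", "band_start", "band_end",
                       "is_micro", "is_micro_group", "sex_annotation",
                       "status")])
  loc$species <- species
  class(loc) <- "chrom_location"
  loc
}

#' Field-by-field equality of two comparative maps
#'
#' Compares species rosters, marker metadata, parsed location fields and rank
#' tables; the raw cell strings are ignored (serialisation normalises dash
#' dialects).
#'
#' @param a,b `comparative_map` objects.
#' @return `TRUE` or `FALSE`.
#' @export
map_equal <- function(a, b) {
  if (!identical(a$species, b$species)) return(FALSE)
  if (!identical(a$markers, b$markers)) return(FALSE)
  la <- a$locations[order(paste(a$locations$symbol, a$locations$species)),
                    c("symbol", "species", .location_fields)]
  lb <- b$locations[order(paste(b$locations$symbol, b$locations$species)),
                    c("symbol", "species", .location_fields)]
  rownames(la) <- rownames(lb) <- NULL
  if (!identical(la, lb)) return(FALSE)
  identical(a$ranks, b$ranks)
}

#' @export
print.comparative_map <- function(x, ...) {
  cat("Comparative cytogenetic map:", nrow(x$markers), "markers x",
      length(x$species), "species\n")
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  n_mapped <- vapply(x$species, function(sp) {
    sum(x$locations$species == sp & x$locations$status == "mapped")
  }, integer(1))
  cat("Mapped locations per species:\n")
  print(n_mapped)
  invisible(x)
}

#' @export
summary.comparative_map <- function(object, ...) {
  tab <- table(object$markers$origin)
  cat("Markers by probe origin:\n")
  print(tab)
  cat("Previously mapped markers:",
      sum(object$markers$previously_mapped), "\n")
  invisible(object)
}

# ---- packaged fixtures -----------------------------------------------------

.extdata <- function(name) {
  system.file("extdata", name, package = "karyoevol", mustWork = TRUE)
}

#' Packaged comparative map of 86 genes across seven sauropsid species
#'
#' The comparative FISH map of 86 functional genes located on chromosomes of
#' the Hokou gecko (GHO), sand lizard (LAG), water monitor (VSA), butterfly
#' lizard (LRE), Japanese four-striped rat snake (EQU) and green anole (ACA),
#' with the chicken (GGA) as outgroup.
#'
#' @return A `comparative_map` with 86 markers and 7 species.
#' @export
gecko_map <- function() {
  read_comparative_map(.extdata("gecko_map.tsv"))
}

#' Packaged karyotype definitions for the study species
#' @return A `karyotype_set` (see [read_karyotypes()]).
#' @export
gecko_karyotypes <- function() {
  read_karyotypes(.extdata("gecko_karyotypes.tsv"))
}

#' Packaged chromosomal landmarks (rDNA clusters, interstitial telomeric site)
#' @return A landmark data.frame (see [read_landmarks()]).
#' @export
gecko_landmarks <- function() {
  read_landmarks(.extdata("gecko_landmarks.tsv"))
}

#' Packaged species tree (gecko basal among the squamates, chicken outgroup)
#' @return A `species_tree` (see [species_tree()]).
#' @export
gecko_tree <- function() {
  species_tree(.extdata("gecko_tree.nwk"), outgroup = "GGA",
               tip_branch_labels = c(GHO = "Gekkota", LAG = "Lacertidae"))
}
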