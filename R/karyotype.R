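#' Read karyotype definitions
#'
#' A karyotype table is tab-separated with columns `species`,
#' `diploid_number`, `fundamental_number` (may be blank), `chromosome`,
#' `morphology` (`metacentric`, `submetacentric`, `subtelocentric`,
#' `acrocentric` or `micro`), `size_class` (`macro`/`micro`), `sex`
#' (`none`, `Z` or `W`; autosome rows are `none`) and `sex_system`
#' (`ZW`, `ZZ-homomorphic` or `unknown`).  One row describes one chromosome
#' pair (autosomes) or one sex chromosome (Z and W listed once each).
#'
#' Validation per species: `2 * n_autosome_rows + n_sex_rows` must equal the
#' stated diploid number, and `morphology = "micro"` forces
#' `size_class = "micro"`.
#'
#' @param file Path to the TSV file.
#' @return A `karyotype_set`: the validated data.frame with class attribute.
#' @export
read_karyotypes <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  need <- c("species", "diploid_number", "chromosome", "morphology",
            "size_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("karyotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"sex" %in% names(tab)) tab$sex <- "none"
  if (!"sex_system" %in% names(tab)) tab$sex_system <- "unknown"
  if (!"fundamental_number" %in% names(tab)) tab$fundamental_number <- ""
  tab$diploid_number <- as.integer(tab$diploid_number)

  ok_morph <- c("metacentric", "submetacentric", "subtelocentric",
                "acrocentric", "micro")
  bad <- setdiff(unique(tab$morphology), ok_morph)
  if (length(bad)) {
    stop("unknown morphology value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$morphology == "micro" & tab$size_class != "micro")) {
    stop("morphology 'micro' requires size_class 'micro'", call. = FALSE)
  }
  for (sp in unique(tab$species)) {
    rows <- tab[tab$species == sp, ]
    n2 <- unique(rows$diploid_number)
    if (length(n2) != 1L) {
      stop("species ", sp, ": inconsistent diploid_number entries",
           call. = FALSE)
    }
    count <- 2L * sum(rows$sex == "none") + sum(rows$sex != "none")
    if (count != n2) {
      stop("species ", sp, ": listed chromosomes imply 2n = ", count,
           " but diploid_number is ", n2, call. = FALSE)
    }
  }
  structure(tab, class = c("karyotype_set", "data.frame"))
}

#' Extract one species' karyotype definition
#'
#' @param karyotypes A `karyotype_set`.
#' @param species Species token.
#' @return A list with `species`, `diploid_number`, `fundamental_number`,
#'   `sex_system` and the per-chromosome data.frame `chromosomes`.
#' @export
karyotype_def <- function(karyotypes, species) {
  rows <- karyotypes[karyotypes$species == species, , drop = FALSE]
  if (!nrow(rows)) stop("no karyotype recorded for species ", species,
                        call. = FALSE)
  list(species = species,
       diploid_number = rows$diploid_number[1],
       fundamental_number = {
         fn <- suppressWarnings(as.integer(rows$fundamental_number[1]))
         if (is.na(fn)) NULL else fn
       },
       sex_system = rows$sex_system[1],
       chromosomes = rows[, c("chromosome", "morphology", "size_class", "sex")])
}

# morphology lookup; NA when unknown
.morphology <- function(karyotypes, species, chromosome) {
  if (is.null(karyotypes)) return(NA_character_)
  i <- which(karyotypes$species == species &
               karyotypes$chromosome == chromosome)
  if (!length(i)) return(NA_character_)
  karyotypes$morphology[i[1]]
}

.size_class <- function(karyotypes, species, chromosome) {
  if (is.null(karyotypes)) return(NA_character_)
  i <- which(karyotypes$species == species &
               karyotypes$chromosome == chromosome)
  if (!length(i)) return(NA_character_)
  karyotypes$size_class[i[1]]
}

# one-armed (fusion-eligible) vs bi-armed morphologies
.is_acro_like <- function(m) m %in% c("acrocentric", "subtelocentric")
.is_biarmed <- function(m) m %in% c("metacentric", "submetacentric")

#' Read a chromosomal landmark table
#'
#' Landmarks are major-rDNA clusters (`rDNA_18S28S`), 5S rDNA clusters
#' (`rDNA_5S`), interstitial telomeric sites (`ITS`) and terminal telomeric
#' signals (`telomere_terminal`).  The `location` column uses the same dialect
#' as the comparative map and is parsed with [parse_location()]; an ITS must
#' name a single chromosome.
#'
#' @param file Path to a TSV with columns `species`, `kind`, `location`,
#'   `note`.
#' @return A data.frame with the parsed location fields appended.
#' @export
read_landmarks <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  need <- c("species", "kind", "location")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("landmark table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"note" %in% names(tab)) tab$note <- ""
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    loc <- .parse_cell(tab$location[i])
    if (is.null(loc)) {
      stop("landmark row ", i, ": cannot parse location ",
           sQuote(tab$location[i]), call. = FALSE)
    }
    loc
  })
  for (f in .location_fields) {
    tab[[f]] <- vapply(parsed, function(p) p[[f]],
                       if (f %in% c("is_micro", "is_micro_group")) logical(1)
                       else character(1))
  }
  its <- tab$kind == "ITS"
  if (any(its & (is.na(tab$chromosome) | tab$is_micro_group))) {
    stop("an ITS landmark must name a single chromosome", call. = FALSE)
  }
  tab
}
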