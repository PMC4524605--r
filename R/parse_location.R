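#' Parse a cytogenetic location string
#'
#' Cytogenetic mapping tables record one location per gene per species using a
#' compact dialect: a chromosome label optionally followed by an arm letter and
#' a band or band interval (`"2q12.2-q21.1"`), a bare `"Micro"` for a signal on
#' an unidentified microchromosome, a numeric range such as `"11-18"` for "one
#' of the small, cytologically indistinguishable chromosomes 11 to 18", a
#' parenthesised sex-chromosome annotation (`"4 (ZW)"`), `"un"` for a probe
#' whose location could not be determined, and a dash (or empty cell) for no
#' data.  `parse_location()` turns one such cell into a structured record.
#'
#' Band intervals accept hyphen or en-dash with optional surrounding
#' whitespace.  An interval whose two ends carry different arm letters (for
#' example `"3p11.1-q11"`, a signal spanning the centromere) is assigned
#' `arm = "whole"` and keeps the arm-qualified band labels.
#'
#' @param raw A single location cell string.
#' @param species Species identifier the cell belongs to (kept as metadata).
#' @return An object of class `chrom_location`: a list with elements
#'   `species`, `chromosome`, `arm` (`"p"`, `"q"` or `"whole"`),
#'   `band_start`, `band_end`, `is_micro`, `is_micro_group`,
#'   `sex_annotation` (`"none"`, `"Z"` or `"ZW"`) and
#'   `status` (`"mapped"`, `"unknown"` or `"missing"`).
#' @examples
#' parse_location("2q12.2 -q21.1", "LRE")
#' parse_location("4 (ZW)", "GHO")
#' parse_location("11-18", "LAG")
#' @export
parse_location <- function(raw, species = NA_character_) {
  loc <- .parse_cell(raw)
  if (is.null(loc)) {
    stop("cannot parse location string ", sQuote(raw),
         if (!is.na(species)) paste0(" (species ", species, ")"), call. = FALSE)
  }
  loc$species <- species
  class(loc) <- "chrom_location"
  loc
}

# en-dash / em-dash normalised to "-" for parsing; canonical writes use en-dash
.DASH <- "–"

.blank_location <- function(status = "missing") {
  list(species = NA_character_, chromosome = NA_character_, arm = "whole",
       band_start = NA_character_, band_end = NA_character_,
       is_micro = FALSE, is_micro_group = FALSE,
       sex_annotation = "none", status = status)
}

# Parse one cell; returns NULL when the token is not understood.
.parse_cell <- function(raw) {
  if (length(raw) != 1L || !is.character(raw)) return(NULL)
  x <- gsub("[–—]", "-", trimws(raw))
  if (is.na(x) || x == "" || grepl("^-+$", x)) return(.blank_location("missing"))
  if (tolower(x) == "un") return(.blank_location("unknown"))

  loc <- .blank_location("mapped")

  sex <- regmatches(x, regexec("\\((Z|ZW)\\)", x))[[1]]
  if (length(sex) == 2L) {
    loc$sex_annotation <- sex[2]
    x <- trimws(gsub("\\((Z|ZW)\\)", "", x))
  }

  if (tolower(x) == "micro") {
    loc$is_micro <- TRUE
    return(loc)
  }
  if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", x)) {
    loc$is_micro_group <- TRUE
    loc$chromosome <- gsub("\\s*-\\s*", .DASH, x)
    return(loc)
  }

  if (grepl("-\\s*$", x) || grepl("^\\s*-", x)) return(NULL)
  parts <- strsplit(x, "\\s*-\\s*")[[1]]
  if (length(parts) > 2L || parts[1] == "") return(NULL)

  band_re <- "[0-9]+(?:\\.[0-9]+)*"
  m <- regmatches(parts[1],
                  regexec(paste0("^(.*?)([pq])(", band_re, ")?$"), parts[1]))[[1]]
  if (length(m) > 0L && nzchar(m[2])) {
    loc$chromosome <- m[2]
    loc$arm <- m[3]
    if (nzchar(m[4])) loc$band_start <- m[4]
  } else if (grepl("^[A-Za-z0-9]+$", parts[1])) {
    loc$chromosome <- parts[1]
  } else {
    return(NULL)
  }

  if (length(parts) == 2L) {
    m2 <- regmatches(parts[2],
                     regexec(paste0("^([pq])?(", band_re, ")$"), parts[2]))[[1]]
    if (length(m2) == 0L || is.na(loc$band_start)) return(NULL)
    arm2 <- if (nzchar(m2[2])) m2[2] else loc$arm
    if (arm2 != loc$arm) {
      # interval spans the centromere: keep arm-qualified band labels
      loc$band_start <- paste0(loc$arm, loc$band_start)
      loc$band_end <- paste0(arm2, m2[3])
      loc$arm <- "whole"
    } else {
      loc$band_end <- m2[3]
    }
  }
  loc
}

#' Format a parsed location back to its canonical string
#'
#' Inverse of [parse_location()].  Band intervals are written with a canonical
#' en-dash and the arm letter repeated on the distal end; missing data is
#' written as an en-dash.
#'
#' @param loc A `chrom_location` object (or a one-row slice of a location
#'   table with the same fields).
#' @return A single character string.
#' @export
format_location <- function(loc) {
  if (loc$status == "missing") return(.DASH)
  if (loc$status == "unknown") return("un")
  if (isTRUE(loc$is_micro)) return("Micro")
  if (isTRUE(loc$is_micro_group)) return(loc$chromosome)
  out <- loc$chromosome
  if (loc$arm %in% c("p", "q")) {
    out <- paste0(out, loc$arm)
    if (!is.na(loc$band_start)) out <- paste0(out, loc$band_start)
    if (!is.na(loc$band_end)) out <- paste0(out, .DASH, loc$arm, loc$band_end)
  } else if (!is.na(loc$band_start)) {
    # centromere-spanning interval; bands carry their own arm letters
    out <- paste0(out, loc$band_start, .DASH, loc$band_end)
  }
  if (loc$sex_annotation != "none") {
    out <- paste0(out, " (", loc$sex_annotation, ")")
  }
  out
}

#' @export
print.chrom_location <- function(x, ...) {
  cat("<chrom_location>", format_location(x))
  if (!is.na(x$species)) cat(" [", x$species, "]", sep = "")
  cat(" status:", x$status, "\n")
  invisible(x)
}

# Ordinal key for a band label within an arm (centromere -> telomere).
# "11.1" < "11.2" < "12" < "21.1"; purely ordinal, never a physical distance.
.band_key <- function(band) {
  if (is.na(band)) return(numeric(0))
  as.numeric(strsplit(band, ".", fixed = TRUE)[[1]])
}
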