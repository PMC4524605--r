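#' Within-chromosome marker order
#'
#' Returns the marker symbols on one chromosome (optionally one arm) of a
#' species, ordered centromere-to-telomere.  An explicit rank column in the
#' map takes precedence; otherwise the fixture row order is used and the
#' result is flagged with provenance `"row_order"` (approximate order).
#'
#' @param map A `comparative_map`.
#' @param species Species token.
#' @param chromosome Chromosome label.
#' @param arm Optional arm (`"p"`/`"q"`); default all arms in row order.
#' @return Character vector of symbols with attribute `provenance`
#'   (`"explicit_rank"` or `"row_order"`).
#' @export
marker_order <- function(map, species, chromosome, arm = NULL) {
  rows <- map$locations[map$locations$species == species &
                          map$locations$status == "mapped" &
                          !map$locations$is_micro, ]
  rows <- rows[.side_chrom(rows) == chromosome, , drop = FALSE]
  if (!is.null(arm)) rows <- rows[rows$arm == arm, , drop = FALSE]
  syms <- rows$symbol[order(match(rows$symbol, map$markers$symbol))]
  prov <- "row_order"
  if (!is.null(map$ranks)) {
    rk <- map$ranks[map$ranks$species == species &
                      map$ranks$symbol %in% syms, ]
    if (nrow(rk) == length(syms)) {
      syms <- rk$symbol[order(rk$rank)]
      prov <- "explicit_rank"
    }
  }
  if (anyDuplicated(syms)) stop("duplicate markers in order", call. = FALSE)
  structure(syms, provenance = prov)
}

#' Breakpoint count between two marker orders
#'
#' Counts adjacencies of `order_a` (including the two virtual ends) that are
#' not adjacent, in either orientation, in `order_b`; the orientation of
#' `order_b` is free, so identical and exactly reversed orders both give 0.
#'
#' @param order_a,order_b Vectors over the same marker set (n >= 1).
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(order_a, order_b) {
  order_a <- as.character(order_a); order_b <- as.character(order_b)
  if (!setequal(order_a, order_b) ||
      length(order_a) != length(order_b)) {
    stop("orders must be over the same marker set", call. = FALSE)
  }
  if (length(order_a) < 1L) stop("orders must have n >= 1", call. = FALSE)
  adj <- function(o) {
    o <- c("(start)", o, "(end)")
    paste(pmin(o[-length(o)], o[-1]), pmax(o[-length(o)], o[-1]), sep = "\r")
  }
  bp <- function(b) sum(!(adj(order_a) %in% adj(b)))
  min(bp(order_b), bp(rev(order_b)))
}

# BFS over the permutation group under segment reversals; returns an
# environment mapping permutation keys to exact reversal distances from the
# identity
.reversal_bfs_cache <- new.env(parent = emptyenv())

.reversal_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.reversal_bfs_cache[[key]])) return(.reversal_bfs_cache[[key]])
  dist <- new.env(parent = emptyenv(), size = 2L * factorial(n))
  pkey <- function(p) paste(p, collapse = ",")
  frontier <- list(seq_len(n))
  assign(pkey(frontier[[1]]), 0L, envir = dist)
  d <- 0L
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  while (length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      for (r in seq_len(nrow(ij))) {
        i <- ij[r, 1]; j <- ij[r, 2]
        q <- p
        q[i:j] <- p[j:i]
        k <- pkey(q)
        if (is.null(dist[[k]])) {
          assign(k, d, envir = dist)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  .reversal_bfs_cache[[key]] <- dist
  dist
}

#' Exact reversal distance for small permutations
#'
#' Minimum number of contiguous-segment reversals transforming `perm` into
#' `reference`, computed by exhaustive breadth-first search over the
#' (unsigned) permutation group.  Exact but exponential: refuses n > 8.
#'
#' @param perm A permutation: an integer vector, or a marker order (character
#'   vector) interpreted relative to `reference`.
#' @param reference Target order; defaults to sorted `perm`.
#' @return Integer distance.
#' @export
reversal_distance_exact <- function(perm, reference = NULL) {
  perm <- as.vector(perm)
  if (is.null(reference)) {
    reference <- if (is.numeric(perm)) sort(perm) else stop(
      "a character permutation needs an explicit reference", call. = FALSE)
  }
  if (!setequal(perm, reference) || length(perm) != length(reference) ||
      anyDuplicated(perm)) {
    stop("perm must be a permutation of reference", call. = FALSE)
  }
  n <- length(perm)
  if (n > 8L) {
    stop("exact reversal distance is limited to n <= 8 ",
         "(exhaustive search over the permutation group)", call. = FALSE)
  }
  if (n <= 1L) return(0L)
  p <- match(perm, reference)
  dist <- .reversal_table(n)
  dist[[paste(p, collapse = ",")]]
}
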