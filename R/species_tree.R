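#' Build a species tree object
#'
#' Wraps an `ape` phylogeny together with a designated outgroup and optional
#' display labels for terminal branches (e.g. naming the branch to the gecko
#' tip "Gekkota").  Internal branches are referred to by the node label of the
#' clade they subtend, so a Newick string with labelled internal nodes gives
#' readable event placements.
#'
#' @param x A Newick string, a path to a Newick file, or an `ape` `phylo`.
#' @param outgroup Tip label used as outgroup for polarization.
#' @param tip_branch_labels Optional named character vector mapping tip names
#'   to branch display labels; unlisted tips use their own name.
#' @return A `species_tree` object.
#' @export
species_tree <- function(x, outgroup, tip_branch_labels = NULL) {
  phy <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1L && grepl("\\(", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(file = x)
  }
  if (is.null(phy)) stop("could not read tree", call. = FALSE)
  if (!outgroup %in% phy$tip.label) {
    stop("outgroup ", sQuote(outgroup), " is not a tip of the tree",
         call. = FALSE)
  }
  structure(list(phylo = phy, outgroup = outgroup,
                 tip_branch_labels = tip_branch_labels),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with", length(x$phylo$tip.label), "tips; outgroup:",
      x$outgroup, "\n")
  cat(ape::write.tree(x$phylo), "\n")
  invisible(x)
}

#' Tip labels of a species tree
#' @param tree A `species_tree`.
#' @return Character vector of tip labels.
#' @export
tree_tips <- function(tree) tree$phylo$tip.label

# topological depth (edges from root) of every tip, named vector
.tip_depths <- function(tree) {
  phy <- tree$phylo
  root <- length(phy$tip.label) + 1L
  depths <- vapply(seq_along(phy$tip.label), function(i) {
    length(ape::nodepath(phy, from = root, to = i)) - 1L
  }, integer(1))
  names(depths) <- phy$tip.label
  depths
}

# display label for the branch above a node (tip or internal)
.branch_label <- function(tree, node) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (node <= ntip) {
    tipname <- phy$tip.label[node]
    if (!is.null(tree$tip_branch_labels) &&
        tipname %in% names(tree$tip_branch_labels)) {
      return(unname(tree$tip_branch_labels[tipname]))
    }
    return(tipname)
  }
  lab <- phy$node.label[node - ntip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", node) else lab
}

# branch above the smallest clade containing all `species`; returns its label
.stem_branch <- function(tree, species) {
  phy <- tree$phylo
  species <- intersect(species, phy$tip.label)
  if (!length(species)) return(NA_character_)
  if (length(species) == 1L) {
    return(.branch_label(tree, match(species, phy$tip.label)))
  }
  node <- ape::getMRCA(phy, species)
  .branch_label(tree, node)
}

# tips descending from the smallest clade containing `species`
.clade_tips <- function(tree, species) {
  phy <- tree$phylo
  species <- intersect(species, phy$tip.label)
  if (length(species) <= 1L) return(species)
  node <- ape::getMRCA(phy, species)
  ape::extract.clade(phy, node)$tip.label
}

#' Re-root a species tree on a different outgroup
#'
#' Used to examine the fusion/fission duality of polarized events: making the
#' formerly derived lineage basal flips the inferred direction of each event.
#'
#' @param tree A `species_tree`.
#' @param outgroup New outgroup tip.
#' @return A new `species_tree`.
#' @export
reroot_tree <- function(tree, outgroup) {
  phy <- ape::root(tree$phylo, outgroup = outgroup, resolve.root = TRUE)
  species_tree(phy, outgroup = outgroup,
               tip_branch_labels = tree$tip_branch_labels)
}
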