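# ---- event container -------------------------------------------------------

.new_events <- function(rows = list()) {
  if (!length(rows)) {
    df <- data.frame(kind = character(), branch = character(),
                     product = character(), confidence = character(),
                     note = character(), stringsAsFactors = FALSE)
    df$operands <- list(); df$evidence <- list(); df$products <- list()
  } else {
    df <- do.call(rbind, rows)
  }
  rownames(df) <- NULL
  class(df) <- c("rearrangement_events", "data.frame")
  df
}

.event <- function(kind, branch, product, operands, evidence, confidence,
                   note = "") {
  df <- data.frame(kind = kind, branch = branch, product = product,
                   confidence = confidence, note = note,
                   stringsAsFactors = FALSE)
  df$operands <- list(operands)
  df$evidence <- list(evidence)
  df$products <- list(product)
  df
}

#' @export
print.rearrangement_events <- function(x, ...) {
  cat("Rearrangement events (", nrow(x), ")\n", sep = "")
  if (nrow(x)) {
    show <- data.frame(kind = x$kind, branch = x$branch,
                       product = vapply(x$products, paste, "",
                                        collapse = "/"),
                       operands = vapply(x$operands, paste, "",
                                         collapse = " + "),
                       support = vapply(x$evidence, function(e)
                         length(unique(unlist(e))), integer(1)),
                       confidence = x$confidence,
                       stringsAsFactors = FALSE)
    print(show, right = FALSE)
  }
  invisible(x)
}

# ---- correspondence classification -----------------------------------------

#' Classify chromosome correspondences between two species
#'
#' Groups the synteny segments of one species pair into per-chromosome
#' correspondence classes.  The informative pattern for fusion/fission
#' inference is `arms_to_two_wholes`: a bi-armed chromosome whose p and q
#' arms each correspond to a distinct chromosome of the other species — the
#' signature of a centric fusion (or, read in the other direction, a centric
#' fission).  Chromosome-to-chromosome matches are `one_to_one_whole`
#' (arm-level detail retained), a one-armed chromosome matching a single arm
#' of a bi-armed partner is `whole_to_arm`, scattered multi-partner matches
#' without arm separation are `segmental`.
#'
#' Classes are produced from the viewpoint of each species in turn;
#' unidentified "Micro" and micro-group sides never form correspondences.
#'
#' @param segments A `segment_table`.
#' @param karyotypes Optional `karyotype_set` for morphology annotation.
#' @return A list of correspondence class records (class
#'   `correspondence_list`); each record has `species`, `chromosome`,
#'   `partner_species`, `pattern`, `arm_detail`, `morphology` and `support`.
#' @export
classify_correspondence <- function(segments, karyotypes = NULL) {
  stopifnot(inherits(segments, "segment_table"))
  sp_a <- attr(segments, "sp_a"); sp_b <- attr(segments, "sp_b")
  out <- c(.classify_side(segments, "a", sp_a, sp_b, karyotypes),
           .classify_side(.swap_segments(segments), "a", sp_b, sp_a,
                          karyotypes))
  class(out) <- "correspondence_list"
  out
}

.swap_segments <- function(segments) {
  df <- segments
  names(df)[match(c("chrom_a", "arm_a", "chrom_b", "arm_b"), names(df))] <-
    c("chrom_b", "arm_b", "chrom_a", "arm_a")
  attr(df, "sp_a") <- attr(segments, "sp_b")
  attr(df, "sp_b") <- attr(segments, "sp_a")
  df
}

.is_pseudo_label <- function(chrom) {
  chrom == "Micro" | grepl("^[0-9]+–[0-9]+$", chrom)
}

.classify_side <- function(segments, side, sp, partner_sp, karyotypes) {
  segs <- segments[!.is_pseudo_label(segments$chrom_a) &
                     !.is_pseudo_label(segments$chrom_b), , drop = FALSE]
  out <- list()
  for (X in .label_sort(segs$chrom_a)) {
    sx <- segs[segs$chrom_a == X, , drop = FALSE]
    # best partner chromosome for one arm of X (max support, ties lexical)
    arm_partner <- function(a) {
      sa <- sx[sx$arm_a == a, , drop = FALSE]
      if (!nrow(sa)) return(NULL)
      supp <- tapply(sa$support_count, sa$chrom_b, sum)
      best <- names(supp)[supp == max(supp)]
      best <- sort(best)[1]
      keep <- sa$chrom_b == best
      list(chrom = best,
           arms = sort(unique(sa$arm_b[keep])),
           support = sort(unique(unlist(sa$support[keep]))))
    }
    det_p <- arm_partner("p"); det_q <- arm_partner("q")
    partners <- sort(unique(sx$chrom_b))
    pattern <- if (!is.null(det_p) && !is.null(det_q)) {
      if (det_p$chrom != det_q$chrom) "arms_to_two_wholes"
      else "one_to_one_whole"
    } else if (length(partners) == 1L) {
      arms_b <- setdiff(unique(sx$arm_b), "whole")
      if (length(arms_b) > 1L) "segmental"
      else if (length(arms_b) == 1L) "whole_to_arm"
      else "one_to_one_whole"
    } else {
      "segmental"
    }
    rec <- list(species = sp, chromosome = X, partner_species = partner_sp,
                pattern = pattern,
                arm_detail = list(p = det_p, q = det_q),
                partners = partners,
                morphology = .morphology(karyotypes, sp, X),
                support = sort(unique(unlist(sx$support))))
    class(rec) <- "correspondence_class"
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' @export
print.correspondence_class <- function(x, ...) {
  cat("<correspondence>", paste0(x$species, x$chromosome), "vs",
      x$partner_species, "-", x$pattern, "\n")
  for (a in c("p", "q")) {
    d <- x$arm_detail[[a]]
    if (!is.null(d)) {
      cat("  ", a, "-> ", x$partner_species, d$chrom,
          " (", length(d$support), " genes)\n", sep = "")
    }
  }
  invisible(x)
}

# ---- polarization ----------------------------------------------------------

# fused/split state of one species for two marker sets: plurality chromosome
# sets; unidentified micro and micro-group placements are uninformative
.set_state <- function(map, species, set1, set2) {
  rows <- map$locations[map$locations$species == species &
                          map$locations$status == "mapped" &
                          !map$locations$is_micro &
                          !map$locations$is_micro_group, ]
  tops <- function(set) {
    ch <- rows$chromosome[rows$symbol %in% set]
    if (!length(ch)) return(NULL)
    tab <- table(ch)
    names(tab)[tab == max(tab)]
  }
  t1 <- tops(set1); t2 <- tops(set2)
  if (is.null(t1) || is.null(t2)) return("unknown")
  if (length(intersect(t1, t2))) "fused" else "split"
}

# ancestral-proto operand name seen from the conservative (partner) species:
# a partner arm collapses to its whole chromosome when that chromosome is
# effectively one-armed (acrocentric-like morphology, or no markers on the
# other arm)
.proto_name <- function(map, karyotypes, species, chrom, arms) {
  arms <- setdiff(arms, "whole")
  if (length(arms) != 1L) return(paste0("proto-", species, chrom))
  a <- arms
  other <- setdiff(c("p", "q"), a)
  other_mapped <- any(map$locations$species == species &
                        map$locations$chromosome == chrom &
                        map$locations$arm == other &
                        map$locations$status == "mapped")
  morph <- .morphology(karyotypes, species, chrom)
  if (!other_mapped && (is.na(morph) || .is_acro_like(morph))) {
    paste0("proto-", species, chrom)
  } else {
    paste0("proto-", species, chrom, a)
  }
}

#' Polarize an arms-to-two-wholes correspondence into a fusion or fission
#'
#' Given a bi-armed chromosome whose arms correspond to two distinct
#' chromosomes elsewhere, decides by outgroup parsimony whether the joined
#' state is derived (centric fusion on the branch leading to the fused
#' lineages) or ancestral (centric fission on the branch leading to the
#' split lineages).  The per-species joined/split states are computed from
#' the two arms' supporting marker sets across the whole map; the designated
#' outgroup anchors the ancestral state, and conflicting or insufficient
#' evidence yields an unpolarized (`ambiguous`) event listing both readings.
#'
#' @param corr A `correspondence_class` with pattern `arms_to_two_wholes`.
#' @param tree A `species_tree`.
#' @param karyotypes Optional `karyotype_set` (operand naming).
#' @param map The `comparative_map` the correspondence came from.
#' @return A one-row `rearrangement_events` table.
#' @export
polarize_fusion_fission <- function(corr, tree, karyotypes = NULL,
                                    map = NULL) {
  if (!inherits(corr, "correspondence_class") ||
      corr$pattern != "arms_to_two_wholes") {
    stop("polarize_fusion_fission() needs an arms_to_two_wholes ",
         "correspondence", call. = FALSE)
  }
  stopifnot(inherits(map, "comparative_map"))
  set_p <- corr$arm_detail$p$support
  set_q <- corr$arm_detail$q$support
  operands <- c(.proto_name(map, karyotypes, corr$partner_species,
                            corr$arm_detail$p$chrom, corr$arm_detail$p$arms),
                .proto_name(map, karyotypes, corr$partner_species,
                            corr$arm_detail$q$chrom, corr$arm_detail$q$arms))
  evidence <- list(set_p, set_q)
  names(evidence) <- operands
  product <- paste0(corr$species, corr$chromosome)

  tips <- intersect(tree_tips(tree), map$species)
  og <- tree$outgroup
  ingroup <- setdiff(tips, og)
  states <- vapply(ingroup, function(sp) .set_state(map, sp, set_p, set_q),
                   character(1))
  og_state <- if (og %in% map$species) .set_state(map, og, set_p, set_q)
              else "unknown"
  fused <- ingroup[states == "fused"]
  split <- ingroup[states == "split"]

  ambiguous <- function() {
    .new_events(list(.event("centric_fusion", NA_character_, product,
                            operands, evidence, "ambiguous",
                            note = "alternatives: centric_fusion|centric_fission")))
  }
  if (og_state == "unknown" && (!length(fused) || !length(split))) {
    return(ambiguous())
  }

  scen <- list()
  if (og_state %in% c("split", "unknown") && length(fused)) {
    inside <- .clade_tips(tree, fused)
    scen$fusion <- list(kind = "centric_fusion",
                        branch = .stem_branch(tree, fused),
                        cost = 1L + length(intersect(split, inside)))
  }
  if (og_state %in% c("fused", "unknown") && length(split)) {
    inside <- .clade_tips(tree, split)
    scen$fission <- list(kind = "centric_fission",
                         branch = .stem_branch(tree, split),
                         cost = 1L + length(intersect(fused, inside)))
  }
  if (!length(scen)) return(ambiguous())
  if (length(scen) == 2L) {
    if (scen$fusion$cost == scen$fission$cost) return(ambiguous())
    scen <- scen[which.min(c(scen$fusion$cost, scen$fission$cost))]
  }
  pick <- scen[[1]]
  .new_events(list(.event(pick$kind, pick$branch, product, operands,
                          evidence, "polarized")))
}

# centric fusion read from morphology: a bi-armed chromosome whose whole
# correspondence is a single effectively-acrocentric partner chromosome; the
# arm sharing fewer markers with the partner is taken as the residual
# lineage-specific proto-chromosome.  Alternative readings (pericentric
# inversion, centromere repositioning) are noted, not asserted.
.morphology_fusion <- function(corr, tree, karyotypes, map) {
  if (corr$pattern != "one_to_one_whole") return(NULL)
  det_p <- corr$arm_detail$p; det_q <- corr$arm_detail$q
  if (is.null(det_p) || is.null(det_q)) return(NULL)
  if (det_p$chrom != det_q$chrom) return(NULL)
  morph_x <- .morphology(karyotypes, corr$species, corr$chromosome)
  morph_y <- .morphology(karyotypes, corr$partner_species, det_p$chrom)
  if (!.is_biarmed(morph_x) || !.is_acro_like(morph_y)) return(NULL)
  residual <- if (length(det_p$support) < length(det_q$support)) "p" else "q"
  product <- paste0(corr$species, corr$chromosome)
  operands <- c(paste0("proto-", corr$species, corr$chromosome, residual),
                paste0("proto-", corr$partner_species, det_p$chrom))
  evidence <- list(character(0), sort(unique(c(det_p$support,
                                               det_q$support))))
  names(evidence) <- operands
  branch <- .stem_branch(tree, corr$species)
  .new_events(list(.event("centric_fusion", branch, product, operands,
                          evidence, "polarized",
                          note = paste("morphology evidence; alternatives:",
                                       "pericentric_inversion|",
                                       "centromere_repositioning"))))
}

# ---- tandem fusion & micro-fusion detection --------------------------------

#' Detect tandem fusions from interstitial telomeric sites and micro-origin
#'
#' An interstitial telomeric site (ITS) is a relic of tandem fusion.  Each
#' ITS landmark on a chromosome with micro-derived markers confined to a
#' single arm yields a `tandem_fusion` event joining that micro-derived arm
#' to the acrocentric proto-chromosome formed by the rest.  Chromosomes whose
#' micro-origin profile is `all_micro` with two or more distinct chicken
#' segments yield a `micro_fusion` event (a chromosome assembled from several
#' ancestral microchromosomes).
#'
#' @param landmarks Landmark data.frame (see [read_landmarks()]).
#' @param profiles Output of [micro_origin_profile()] for `species`.
#' @param map A `comparative_map`.
#' @param species Species being examined.
#' @param toxicofera Micro/macro evidence species.
#' @param karyotypes Optional `karyotype_set`.
#' @param tree Optional `species_tree` (branch naming; the species' terminal
#'   branch label is used).
#' @param chicken Chicken token (default `"GGA"`).
#' @return A `rearrangement_events` table.
#' @export
detect_tandem_fusion <- function(landmarks, profiles, map, species,
                                 toxicofera = c("VSA", "LRE", "EQU"),
                                 karyotypes = NULL, tree = NULL,
                                 chicken = "GGA") {
  branch <- if (!is.null(tree) && species %in% tree_tips(tree)) {
    .stem_branch(tree, species)
  } else species
  md <- micro_derived_markers(map, toxicofera, karyotypes)
  rows <- list()

  its <- landmarks[landmarks$species == species & landmarks$kind == "ITS", ,
                   drop = FALSE]
  for (i in seq_len(nrow(its))) {
    C <- its$chromosome[i]
    on_c <- map$locations[map$locations$species == species &
                            map$locations$status == "mapped" &
                            !map$locations$is_micro &
                            !map$locations$is_micro_group &
                            map$locations$chromosome == C, ]
    micro_arms <- unique(on_c$arm[on_c$symbol %in% md])
    micro_arms <- intersect(micro_arms, c("p", "q"))
    if (length(micro_arms) != 1L) next
    a <- micro_arms; other <- setdiff(c("p", "q"), a)
    operands <- c(paste0(species, C, a), paste0("proto-", species, C, other))
    evidence <- list(sort(on_c$symbol[on_c$symbol %in% md & on_c$arm == a]),
                     sort(on_c$symbol[on_c$arm == other]))
    names(evidence) <- operands
    rows[[length(rows) + 1L]] <-
      .event("tandem_fusion", branch, paste0(species, C), operands, evidence,
             "polarized", note = "ITS relic")
  }

  comp <- profiles[profiles$classification == "all_micro" &
                     profiles$segment_count >= 2L &
                     !.is_pseudo_label(profiles$chromosome), , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    genes <- sort(unique(comp$genes[[i]]))
    segs <- .chicken_segments(map, genes, chicken)
    operands <- paste0("micro(", chicken, segs, ")")
    evidence <- lapply(segs, function(s) {
      .chicken_segment_genes(map, genes, chicken, s)
    })
    names(evidence) <- operands
    rows[[length(rows) + 1L]] <-
      .event("micro_fusion", branch,
             paste0(species, comp$chromosome[i]), operands, evidence,
             "polarized", note = "micro-origin profile")
  }
  .new_events(rows)
}

.chicken_segments <- function(map, genes, chicken) {
  g <- map$locations[map$locations$species == chicken &
                       map$locations$status == "mapped" &
                       !map$locations$is_micro & !map$locations$is_micro_group &
                       map$locations$symbol %in% genes, ]
  sort(unique(ifelse(g$arm %in% c("p", "q"),
                     paste0(g$chromosome, g$arm), g$chromosome)))
}

.chicken_segment_genes <- function(map, genes, chicken, seg) {
  g <- map$locations[map$locations$species == chicken &
                       map$locations$status == "mapped" &
                       map$locations$symbol %in% genes, ]
  tok <- ifelse(g$arm %in% c("p", "q"), paste0(g$chromosome, g$arm),
                g$chromosome)
  sort(unique(g$symbol[tok == seg]))
}

# ---- scenario inference ----------------------------------------------------

#' Infer a polarized karyotype rearrangement scenario
#'
#' Runs the full inference chain: pairwise synteny segments, correspondence
#' classification, outgroup-parsimony polarization of centric
#' fusions/fissions, morphology-based fusion reading for bi-armed chromosomes
#' matching a single ancestral acrocentric, and tandem-/micro-fusion
#' detection from landmarks and micro-origin profiles.  Events supported by
#' several species pairs are merged (operand naming follows the most basal
#' partner species); output order is deterministic (branch, then product,
#' then kind).
#'
#' @param map A `comparative_map`.
#' @param karyotypes A `karyotype_set`.
#' @param landmarks Landmark data.frame.
#' @param tree A `species_tree` whose tips cover the species used.
#' @param config List of options: `pairs` (list of species pairs to compare;
#'   default: most basal ingroup tip against every other non-excluded ingroup
#'   tip), `exclude` (species never used as comparison partner; default
#'   `"ACA"`, whose map is sparse and chromosome-number based),
#'   `detect_species` (lineages scanned for tandem/micro fusions; default the
#'   ingroup species not in `toxicofera`), `toxicofera`, `chicken`,
#'   `min_operand_support` (genes required on each arm; default 1).
#' @return A `rearrangement_events` table.
#' @export
infer_scenario <- function(map, karyotypes, landmarks, tree,
                           config = list()) {
  cfg <- utils::modifyList(
    list(pairs = NULL, exclude = "ACA", detect_species = NULL,
         toxicofera = c("VSA", "LRE", "EQU"), chicken = "GGA",
         min_operand_support = 1L),
    config)
  tips <- intersect(tree_tips(tree), map$species)
  ingroup <- setdiff(tips, tree$outgroup)

  if (is.null(cfg$pairs)) {
    depths <- .tip_depths(tree)
    cand <- setdiff(ingroup, cfg$exclude)
    if (length(cand) >= 2L) {
      basal <- cand[which.min(depths[cand])]
      cfg$pairs <- lapply(setdiff(cand, basal), function(sp) c(basal, sp))
    } else {
      cfg$pairs <- list()
    }
  }
  for (p in cfg$pairs) {
    missing_sp <- setdiff(p, map$species)
    if (length(missing_sp)) {
      stop("species ", paste(missing_sp, collapse = ", "),
           " not present in the map", call. = FALSE)
    }
  }
  if (is.null(cfg$detect_species)) {
    cfg$detect_species <- setdiff(ingroup, c(cfg$toxicofera, cfg$exclude))
  }

  depths <- .tip_depths(tree)
  cand <- list(); cand_depth <- integer(0)
  for (p in cfg$pairs) {
    segs <- segment_table(map, p[1], p[2])
    classes <- classify_correspondence(segs, karyotypes)
    for (cls in classes) {
      ev <- NULL
      if (cls$pattern == "arms_to_two_wholes") {
        supp_ok <- length(cls$arm_detail$p$support) >=
          cfg$min_operand_support &&
          length(cls$arm_detail$q$support) >= cfg$min_operand_support
        if (supp_ok) {
          ev <- polarize_fusion_fission(cls, tree, karyotypes, map)
        }
      } else {
        ev <- .morphology_fusion(cls, tree, karyotypes, map)
      }
      if (!is.null(ev) && nrow(ev)) {
        cand[[length(cand) + 1L]] <- ev
        pd <- depths[cls$partner_species]
        cand_depth <- c(cand_depth, if (is.na(pd)) 99L else pd)
      }
    }
  }
  merged <- .merge_events(cand, cand_depth)

  extra <- list()
  for (sp in cfg$detect_species) {
    profiles <- micro_origin_profile(map, sp, cfg$toxicofera, karyotypes,
                                     cfg$chicken)
    ev <- detect_tandem_fusion(landmarks, profiles, map, sp,
                               cfg$toxicofera, karyotypes, tree,
                               cfg$chicken)
    if (nrow(ev)) extra[[length(extra) + 1L]] <- ev
  }
  all_rows <- c(if (nrow(merged)) list(merged) else list(), extra)
  out <- if (length(all_rows)) {
    .new_events(lapply(all_rows, function(d) d))
  } else {
    .new_events()
  }
  if (nrow(out)) {
    ord <- order(ifelse(is.na(out$branch), "~", out$branch), out$product,
                 out$kind)
    out <- out[ord, ]
    rownames(out) <- NULL
    class(out) <- c("rearrangement_events", "data.frame")
  }
  out
}

# merge candidate events describing the same rearrangement: same kind and
# branch, operand evidence sets overlapping pairwise; operand names are kept
# from the candidate whose partner species is most basal
.merge_events <- function(cand, cand_depth) {
  if (!length(cand)) return(.new_events())
  ord <- order(cand_depth,
               vapply(cand, function(e) e$product[1], character(1)))
  cand <- cand[ord]
  merged <- list()
  for (e in cand) {
    hit <- 0L
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (!identical(m$kind[1], e$kind[1])) next
      if (!identical(m$branch[1], e$branch[1])) next
      if (.operands_match(m$evidence[[1]], e$evidence[[1]])) { hit <- j; break }
    }
    if (hit == 0L) {
      merged[[length(merged) + 1L]] <- e
    } else {
      m <- merged[[hit]]
      pairing <- .operand_pairing(m$evidence[[1]], e$evidence[[1]])
      ev <- m$evidence[[1]]
      for (k in 1:2) {
        ev[[k]] <- sort(unique(c(ev[[k]], e$evidence[[1]][[pairing[k]]])))
      }
      m$evidence[[1]] <- ev
      m$products[[1]] <- sort(unique(c(m$products[[1]], e$products[[1]])))
      merged[[hit]] <- m
    }
  }
  .new_events(merged)
}

.operand_pairing <- function(ev1, ev2) {
  if (length(ev1) != 2L || length(ev2) != 2L) return(NULL)
  direct <- length(intersect(ev1[[1]], ev2[[1]])) > 0L &&
    length(intersect(ev1[[2]], ev2[[2]])) > 0L
  crossed <- length(intersect(ev1[[1]], ev2[[2]])) > 0L &&
    length(intersect(ev1[[2]], ev2[[1]])) > 0L
  if (direct) c(1L, 2L) else if (crossed) c(2L, 1L) else NULL
}

.operands_match <- function(ev1, ev2) {
  !is.null(.operand_pairing(ev1, ev2))
}

# ---- qualitative inversion flags -------------------------------------------

#' Flag putative inversions from marker-order differences
#'
#' For every chromosome/arm pair sharing at least `min_shared` markers,
#' compares the two within-chromosome marker orders and flags a putative
#' (paracentric) inversion when the orders differ beyond a whole-segment
#' reversal.  Orders taken from fixture row order are approximate, so flags
#' are qualitative: events are emitted unpolarized, and no minimal-event
#' claim is attached.
#'
#' @param map A `comparative_map`.
#' @param sp_a,sp_b Species pair.
#' @param min_shared Minimum shared markers per segment (default 3).
#' @return A `rearrangement_events` table of `paracentric_inversion` flags.
#' @export
flag_inversions <- function(map, sp_a, sp_b, min_shared = 3L) {
  segs <- segment_table(map, sp_a, sp_b)
  segs <- segs[segs$support_count >= min_shared &
                 !.is_pseudo_label(segs$chrom_a) &
                 !.is_pseudo_label(segs$chrom_b), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(segs))) {
    genes <- segs$support[[i]]
    oa <- marker_order(map, sp_a, segs$chrom_a[i])
    ob <- marker_order(map, sp_b, segs$chrom_b[i])
    oa <- oa[oa %in% genes]; ob <- ob[ob %in% genes]
    if (length(oa) < min_shared || !setequal(oa, ob)) next
    if (breakpoint_count(oa, ob) > 0L) {
      side_a <- paste0(sp_a, segs$chrom_a[i],
                       if (segs$arm_a[i] != "whole") segs$arm_a[i] else "")
      side_b <- paste0(sp_b, segs$chrom_b[i],
                       if (segs$arm_b[i] != "whole") segs$arm_b[i] else "")
      operands <- c(side_a, side_b)
      evidence <- list(genes, genes); names(evidence) <- operands
      prov <- attr(oa, "provenance")
      rows[[length(rows) + 1L]] <-
        .event("paracentric_inversion", NA_character_, side_b, operands,
               evidence, "ambiguous",
               note = paste0("order provenance: ",
                             if (is.null(prov)) "row_order" else prov))
    }
  }
  .new_events(rows)
}
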