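# ---- simulator configuration ----------------------------------------------

#' Configure a karyotype-evolution simulation
#'
#' The simulated ancestor is a karyotype of one-armed (acrocentric)
#' macrochromosomes plus microchromosomes, represented pseudo-haploid (one
#' copy per pair; sex chromosomes are not simulated).  Gene markers are
#' placed on the ancestral chromosomes in random (seeded) order, and
#' per-branch event lists evolve the karyotype along a species tree.
#'
#' @param n_macro Number of ancestral acrocentric macrochromosomes
#'   (default 19, a gecko-like graded acrocentric complement).
#' @param n_micro Number of ancestral microchromosomes (default 12).
#' @param markers_per_macro,markers_per_micro Markers sampled per ancestral
#'   chromosome (defaults 3 and 2).
#' @param branch_events Named list: branch label (tip name or internal node
#'   label) -> list of event specs.  An event spec is a list with `kind`
#'   (`"centric_fusion"`, `"centric_fission"`, `"tandem_fusion"`,
#'   `"inversion"`) and optional `operands` (chromosome labels; omitted or
#'   `"random"` draws uniformly from the currently eligible chromosomes).
#' @param its_relic_probability Probability that a tandem fusion leaves a
#'   detectable interstitial telomeric site (default 1).
#' @param seed Integer seed driving marker placement and random operand
#'   draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_macro = 19L, n_micro = 12L,
                       markers_per_macro = 3L, markers_per_micro = 2L,
                       branch_events = list(),
                       its_relic_probability = 1, seed = 1L) {
  stopifnot(n_macro >= 1L, n_micro >= 0L,
            markers_per_macro >= 0L, markers_per_micro >= 0L,
            its_relic_probability >= 0, its_relic_probability <= 1)
  structure(list(n_macro = as.integer(n_macro),
                 n_micro = as.integer(n_micro),
                 markers_per_macro = as.integer(markers_per_macro),
                 markers_per_micro = as.integer(markers_per_micro),
                 branch_events = branch_events,
                 its_relic_probability = its_relic_probability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample() that never interprets a length-1 vector as 1:n
.resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# chromosome record: label, type ("acro"/"bi"/"micro"-sized one-armed),
# size ("macro"/"micro"), arms p/q (markers centromere -> telomere),
# its: character vector of arms carrying an interstitial telomeric relic
.chrom <- function(label, type, size, p = character(0), q = character(0),
                   its = character(0)) {
  list(label = label, type = type, size = size,
       arms = list(p = p, q = q), its = its)
}

.ancestral_state <- function(config) {
  state <- list()
  m <- 0L
  mk <- function(k) sprintf("g%03d", k)
  for (i in seq_len(config$n_macro)) {
    genes <- if (config$markers_per_macro) {
      m <- m + config$markers_per_macro
      mk((m - config$markers_per_macro + 1L):m)
    } else character(0)
    state[[length(state) + 1L]] <-
      .chrom(paste0("A", i), "acro", "macro", q = genes)
  }
  for (i in seq_len(config$n_micro)) {
    genes <- if (config$markers_per_micro) {
      m <- m + config$markers_per_micro
      mk((m - config$markers_per_micro + 1L):m)
    } else character(0)
    state[[length(state) + 1L]] <-
      .chrom(paste0("M", i), "micro", "micro", q = genes)
  }
  # random within-chromosome marker order
  for (i in seq_along(state)) {
    q <- state[[i]]$arms$q
    if (length(q) > 1L) state[[i]]$arms$q <- .resample(q, length(q))
  }
  names(state) <- vapply(state, `[[`, "", "label")
  state
}

.one_armed <- function(ch) ch$type %in% c("acro", "micro")

# apply one event spec; returns list(state, record) with the resolved
# operands and the markers carried by each operand at the time of the event
.apply_event <- function(state, spec, config, record_its = TRUE) {
  kind <- spec$kind
  ops <- spec$operands
  arm_used <- NULL; span_used <- NULL
  labels <- names(state)
  pick <- function(eligible, n) {
    if (length(eligible) < n) {
      stop("no eligible chromosome for a random ", kind, " event",
           call. = FALSE)
    }
    .resample(eligible, n)
  }
  resolve <- function(n, eligible) {
    if (is.null(ops) || identical(ops, "random")) return(pick(eligible, n))
    missing_op <- setdiff(ops, labels)
    if (length(missing_op)) {
      stop(kind, " names nonexistent chromosome(s): ",
           paste(missing_op, collapse = ", "), call. = FALSE)
    }
    ops
  }
  its_left <- NA
  if (kind == "centric_fusion") {
    eligible <- labels[vapply(state, function(ch)
      .one_armed(ch) && ch$size == "macro", logical(1))]
    ops <- resolve(2L, eligible)
    a <- state[[ops[1]]]; b <- state[[ops[2]]]
    if (!.one_armed(a) || !.one_armed(b)) {
      stop("centric fusion requires two one-armed chromosomes", call. = FALSE)
    }
    size <- if (a$size == "micro" && b$size == "micro") "micro" else "macro"
    new <- .chrom(paste0(a$label, b$label), "bi", size,
                  p = a$arms$q, q = b$arms$q)
    state[[ops[1]]] <- NULL; state[[ops[2]]] <- NULL
    state[[new$label]] <- new
    op_markers <- list(new$arms$p, new$arms$q)
  } else if (kind == "centric_fission") {
    eligible <- labels[vapply(state, function(ch) ch$type == "bi",
                              logical(1))]
    ops <- resolve(1L, eligible)
    x <- state[[ops[1]]]
    if (x$type != "bi") {
      stop("centric fission requires a bi-armed chromosome", call. = FALSE)
    }
    n1 <- .chrom(paste0(x$label, "A"), "acro", x$size, q = x$arms$p)
    n2 <- .chrom(paste0(x$label, "B"), "acro", x$size, q = x$arms$q)
    state[[ops[1]]] <- NULL
    state[[n1$label]] <- n1; state[[n2$label]] <- n2
    op_markers <- list(n1$arms$q, n2$arms$q)
  } else if (kind == "tandem_fusion") {
    micros <- labels[vapply(state, function(ch) ch$size == "micro",
                            logical(1))]
    macros <- labels[vapply(state, function(ch) ch$size == "macro",
                            logical(1))]
    if (is.null(ops) || identical(ops, "random")) {
      ops <- c(pick(micros, 1L), pick(macros, 1L))
    }
    mi <- state[[ops[1]]]; tg <- state[[ops[2]]]
    if (is.null(mi) || is.null(tg)) {
      stop("tandem_fusion names nonexistent chromosome(s)", call. = FALSE)
    }
    if (mi$size != "micro") {
      stop("tandem fusion joins a microchromosome to a chromosome end",
           call. = FALSE)
    }
    arm <- if (!is.null(spec$arm)) spec$arm
           else if (tg$type == "bi") .resample(c("p", "q")) else "q"
    arm_used <- arm
    tg$arms[[arm]] <- c(tg$arms[[arm]], mi$arms$q)
    its_left <- stats::runif(1) <= config$its_relic_probability
    if (its_left && record_its) tg$its <- c(tg$its, arm)
    state[[ops[1]]] <- NULL
    state[[tg$label]] <- tg
    op_markers <- list(mi$arms$q, setdiff(tg$arms[[arm]], mi$arms$q))
  } else if (kind == "inversion") {
    eligible <- labels[vapply(state, function(ch)
      any(lengths(ch$arms) >= 2L), logical(1))]
    ops <- resolve(1L, eligible)
    x <- state[[ops[1]]]
    arms2 <- names(x$arms)[lengths(x$arms) >= 2L]
    arm <- if (!is.null(spec$arm)) spec$arm else .resample(arms2)
    g <- x$arms[[arm]]
    span <- if (!is.null(spec$span)) spec$span else {
      i <- .resample(seq_len(length(g) - 1L)); c(i, .resample((i + 1L):length(g)))
    }
    arm_used <- arm; span_used <- span
    g[span[1]:span[2]] <- rev(g[span[1]:span[2]])
    x$arms[[arm]] <- g
    state[[ops[1]]] <- x
    op_markers <- list(g)
  } else {
    stop("unknown simulated event kind: ", kind, call. = FALSE)
  }
  list(state = state,
       record = list(kind = kind, operands = ops, arm = arm_used,
                     span = span_used, operand_markers = op_markers,
                     its = its_left))
}

#' Evolve a karyotype along a species tree
#'
#' Places markers on the ancestral karyotype and applies the configured
#' events branch by branch in root-to-tip order.  Returns the comparative
#' map observed at the tips (with explicit rank columns, so order-based
#' inference is exact), the landmark table (interstitial telomeric relics of
#' tandem fusions), and the full ground-truth history.
#'
#' Identified macrochromosomes are emitted with their lineage labels and arm
#' letters; microchromosomes are emitted as `"Micro"`, mimicking FISH maps
#' in which individual microchromosomes cannot be told apart.
#'
#' @param config A `sim_config`.
#' @param tree A `species_tree`; branch events are keyed by tip names and
#'   internal node labels.
#' @return A list of class `karyo_sim` with elements `map` (a
#'   `comparative_map`), `landmarks`, `karyotypes` (a `karyotype_set`) and
#'   `history` (a `sim_history`).
#' @export
sim_evolve <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "species_tree"))
  set.seed(config$seed)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L

  state0 <- .ancestral_state(config)
  marker_origin <- unlist(unname(lapply(state0, function(ch) {
    stats::setNames(rep(ch$label, length(ch$arms$q)), ch$arms$q)
  })))

  tip_states <- vector("list", ntip)
  names(tip_states) <- phy$tip.label
  applied <- list()

  recurse <- function(node, state) {
    children <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in children) {
      st <- state
      lab <- .branch_label(tree, child)
      for (spec in config$branch_events[[lab]] %||% list()) {
        res <- .apply_event(st, spec, config)
        st <- res$state
        applied[[length(applied) + 1L]] <<- c(list(branch = lab),
                                              res$record)
      }
      if (child <= ntip) {
        tip_states[[phy$tip.label[child]]] <<- st
      } else {
        recurse(child, st)
      }
    }
  }
  recurse(root, state0)

  history <- structure(list(ancestral = state0, applied = applied,
                            tip_states = tip_states,
                            marker_origin = marker_origin,
                            tree = tree, config = config),
                       class = "sim_history")
  c(.sim_outputs(history), list(history = history))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# observable outputs (map, landmarks, karyotypes) from a set of tip states
.sim_outputs <- function(history) {
  tip_states <- history$tip_states
  tips <- names(tip_states)
  markers <- sort(names(history$marker_origin))

  loc_rows <- list(); rank_rows <- list()
  for (sp in tips) {
    st <- tip_states[[sp]]
    for (ch in st) {
      for (arm in c("p", "q")) {
        genes <- ch$arms[[arm]]
        for (k in seq_along(genes)) {
          if (ch$size == "micro") {
            raw <- "Micro"
          } else if (ch$type == "bi") {
            raw <- paste0(ch$label, arm)
          } else {
            raw <- ch$label
          }
          loc <- .parse_cell(raw)
          loc_rows[[length(loc_rows) + 1L]] <-
            data.frame(symbol = genes[k], species = sp, raw = raw,
                       chromosome = loc$chromosome, arm = loc$arm,
                       band_start = loc$band_start, band_end = loc$band_end,
                       is_micro = loc$is_micro,
                       is_micro_group = loc$is_micro_group,
                       sex_annotation = loc$sex_annotation,
                       status = loc$status, stringsAsFactors = FALSE)
          rank_rows[[length(rank_rows) + 1L]] <-
            data.frame(symbol = genes[k], species = sp, rank = k,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  locations <- do.call(rbind, loc_rows)
  locations <- locations[order(match(locations$symbol, markers),
                               match(locations$species, tips)), ]
  rownames(locations) <- NULL
  ranks <- do.call(rbind, rank_rows)
  ranks <- ranks[order(match(ranks$symbol, markers),
                       match(ranks$species, tips)), ]
  rownames(ranks) <- NULL

  marker_df <- data.frame(symbol = markers, origin = "simulated",
                          length_bp = NA_character_,
                          accessions = NA_character_,
                          previously_mapped = FALSE,
                          stringsAsFactors = FALSE)
  map <- .new_comparative_map(tips, marker_df, locations, ranks)

  lm_rows <- list()
  for (sp in tips) {
    for (ch in tip_states[[sp]]) {
      for (arm in ch$its) {
        lm_rows[[length(lm_rows) + 1L]] <-
          data.frame(species = sp, kind = "ITS",
                     location = paste0(ch$label,
                                       if (ch$type == "bi") arm else ""),
                     note = "tandem fusion relic", stringsAsFactors = FALSE)
      }
    }
  }
  landmarks <- if (length(lm_rows)) {
    tab <- do.call(rbind, lm_rows)
    parsed <- lapply(tab$location, .parse_cell)
    for (f in .location_fields) {
      tab[[f]] <- vapply(parsed, function(p) p[[f]],
                         if (f %in% c("is_micro", "is_micro_group"))
                           logical(1) else character(1))
    }
    tab
  } else {
    data.frame(species = character(), kind = character(),
               location = character(), note = character(),
               stringsAsFactors = FALSE)
  }

  k_rows <- list()
  for (sp in tips) {
    st <- tip_states[[sp]]
    for (ch in st) {
      morph <- switch(ch$type, acro = "acrocentric", bi = "submetacentric",
                      micro = "micro")
      if (ch$size == "micro" && ch$type != "bi") morph <- "micro"
      k_rows[[length(k_rows) + 1L]] <-
        data.frame(species = sp, diploid_number = 2L * length(st),
                   fundamental_number = "", chromosome = ch$label,
                   morphology = morph,
                   size_class = ch$size, sex = "none",
                   sex_system = "unknown", stringsAsFactors = FALSE)
    }
  }
  karyotypes <- do.call(rbind, k_rows)
  class(karyotypes) <- c("karyotype_set", "data.frame")

  structure(list(map = map, landmarks = landmarks, karyotypes = karyotypes),
            class = "karyo_sim")
}

#' Replay a simulation history from the ancestor
#'
#' Re-applies the recorded event log to the ancestral karyotype and checks
#' that every tip karyotype is reproduced exactly.
#'
#' @param history A `sim_history`.
#' @return Invisibly `TRUE` when all tips replay exactly; otherwise an error.
#' @export
sim_replay <- function(history) {
  tree <- history$tree
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  by_branch <- split(history$applied,
                     vapply(history$applied, `[[`, "", "branch"))
  replay_tips <- vector("list", ntip)
  names(replay_tips) <- phy$tip.label

  apply_recorded <- function(state, rec) {
    res <- .apply_event(state, list(kind = rec$kind, operands = rec$operands,
                                    arm = rec$arm, span = rec$span),
                        history$config, record_its = isTRUE(rec$its))
    res$state
  }
  recurse <- function(node, state) {
    children <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in children) {
      st <- state
      lab <- .branch_label(tree, child)
      for (rec in by_branch[[lab]] %||% list()) st <- apply_recorded(st, rec)
      if (child <= ntip) replay_tips[[phy$tip.label[child]]] <<- st
      else recurse(child, st)
    }
  }
  recurse(root, history$ancestral)
  for (sp in names(replay_tips)) {
    a <- replay_tips[[sp]]; b <- history$tip_states[[sp]]
    strip <- function(st) lapply(st, function(ch) ch[c("label", "type",
                                                       "size", "arms")])
    if (!identical(strip(a), strip(b))) {
      stop("replay does not reproduce the karyotype of tip ", sp,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Chromosome census of a simulated tip
#'
#' @param history A `sim_history`.
#' @param tip Tip name.
#' @return List with `diploid_number_analog` (twice the pseudo-haploid
#'   chromosome count), `chromosome_count` and `micro_count`.
#' @export
chromosome_census <- function(history, tip) {
  st <- history$tip_states[[tip]]
  if (is.null(st)) stop("unknown tip: ", tip, call. = FALSE)
  micro <- sum(vapply(st, function(ch) ch$size == "micro", logical(1)))
  list(diploid_number_analog = 2L * length(st),
       chromosome_count = length(st), micro_count = micro)
}

#' Score recovery of simulated centric fusions
#'
#' Compares an inferred event list against the simulator's ground truth.  A
#' true fusion is scorable when both operands carried at least `min_markers`
#' markers; it counts as recovered when an inferred `centric_fusion` on the
#' same branch pairs its two operand evidence sets with the two true operand
#' marker sets (each inferred set non-empty and fully contained in its true
#' set).
#'
#' @param history A `sim_history`.
#' @param events A `rearrangement_events` table (e.g. from
#'   [infer_scenario()]).
#' @param min_markers Markers required per operand for a fusion to enter the
#'   denominator (default 2).
#' @return List with `n_true`, `n_recovered` and `rate`.
#' @export
score_fusion_recovery <- function(history, events, min_markers = 2L) {
  truths <- Filter(function(r) {
    r$kind == "centric_fusion" &&
      all(lengths(r$operand_markers) >= min_markers)
  }, history$applied)
  n_rec <- 0L
  for (tr in truths) {
    found <- FALSE
    for (i in seq_len(nrow(events))) {
      if (events$kind[i] != "centric_fusion") next
      if (!identical(events$branch[i], tr$branch)) next
      ev <- events$evidence[[i]]
      if (length(ev) != 2L || !length(ev[[1]]) || !length(ev[[2]])) next
      t1 <- tr$operand_markers[[1]]; t2 <- tr$operand_markers[[2]]
      direct <- all(ev[[1]] %in% t1) && all(ev[[2]] %in% t2)
      crossed <- all(ev[[1]] %in% t2) && all(ev[[2]] %in% t1)
      if (direct || crossed) { found <- TRUE; break }
    }
    if (found) n_rec <- n_rec + 1L
  }
  n_true <- length(truths)
  list(n_true = n_true, n_recovered = n_rec,
       rate = if (n_true) n_rec / n_true else NA_real_)
}
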