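#' Unit-cost event model for mutational step counting
#'
#' Every elementary event costs one step by default. A segmental
#' duplication whose copy lands on a different chromosome is a
#' *translocated* segmental duplication and decomposes into duplication +
#' translocation (two steps).
#'
#' @param costs optional named numeric overriding default costs.
#' @export
event_model <- function(costs = NULL) {
  base <- c(TANDEM_DUP = 1, SEG_DUP = 1, TRANSLOCATION = 1, WGD = 1,
            GENE_LOSS = 1, SEGMENT_LOSS = 1, INVERSION = 1, FISSION = 1)
  if (!is.null(costs)) {
    if (any(costs <= 0) || any(costs != round(costs)))
      stop("event_model: costs must be positive integers")
    base[names(costs)] <- costs
  }
  structure(as.list(base), class = "event_model")
}

event_cost <- function(ev, model) {
  if (is.null(model[[ev$kind]])) stop("step_count: unknown event kind '", ev$kind, "'")
  cost <- model[[ev$kind]]
  if (ev$kind == "SEG_DUP" && !is.null(ev$target_chrom) &&
      !identical(ev$target_chrom, ev$chrom))
    cost <- cost + model[["TRANSLOCATION"]]
  cost
}

#' Branch-anchored evolutionary scenario
#'
#' Binds an ordered event list to a rooted species tree and an ancestral
#' genome. Events with `branch = NA` apply to the ancestor before the first
#' split; other events apply on the named branch, in list order, branches
#' visited in preorder. `canonical` maps the gene ids that exist after
#' replay to gene-class names (e.g. `VTR1_b` -> `OTR`), so predictions can
#' be compared with observed repertoires.
#'
#' @param tree Newick string or `phylo`.
#' @param ancestor named list chromosome -> gene id vector, or
#'   [genome_table()].
#' @param events list of [event()]s.
#' @param canonical named character vector gene id -> class name.
#' @export
scenario <- function(tree, ancestor, events, canonical = NULL) {
  structure(list(tree = read_species_tree(tree), ancestor = ancestor,
                 events = events, canonical = canonical), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", length(x$events), "events on",
      length(x$tree$tip.label), "leaves\n")
  for (ev in x$events) print(ev)
  invisible(x)
}

#' Concatenate scenarios sharing a tree (step counts are additive)
#' @export
scenario_concat <- function(a, b) {
  scenario(a$tree, a$ancestor, c(a$events, b$events),
           c(a$canonical, b$canonical[setdiff(names(b$canonical), names(a$canonical))]))
}

#' Mutational step count of a scenario
#'
#' Sum of per-event costs under an [event_model()], after decomposing
#' compound events (translocated segmental duplications) into elementary
#' ones. Additive over scenario concatenation.
#' @export
step_count <- function(scn, model = event_model()) {
  evs <- if (inherits(scn, "scenario")) scn$events else scn
  sum(vapply(evs, event_cost, numeric(1), model = model))
}

#' Replay a scenario into per-leaf repertoires
#'
#' Deterministically replays the event list down the tree (delegating to
#' [apply_event()]) and reports, per leaf, which gene classes are present
#' and which class pairs share a chromosome.
#'
#' @param scn a [scenario()].
#' @return class `scenario_prediction`: list(presence = per-leaf named
#'   vector class -> chromosome, colocation = data.frame(lineage, a, b),
#'   node_genomes).
#' @export
apply_scenario <- function(scn) {
  tree <- scn$tree
  anc <- if (inherits(scn$ancestor, "genome_table")) scn$ancestor
         else ancestor_table(scn$ancestor)
  labels <- node_labels(tree)
  branch_of <- vapply(scn$events, function(e) as.character(e$branch %||% NA),
                      character(1))
  state <- anc
  for (ev in scn$events[is.na(branch_of)]) state <- apply_event(state, ev)
  node_genomes <- list()
  node_genomes[[labels[root_node(tree)]]] <- state
  for (node in setdiff(preorder_nodes(tree), root_node(tree))) {
    lab <- labels[node]
    st <- node_genomes[[labels[parent_node(tree, node)]]]
    for (ev in scn$events[!is.na(branch_of) & branch_of == lab])
      st <- apply_event(st, ev)
    node_genomes[[lab]] <- st
  }
  canon <- scn$canonical %||% character()
  presence <- lapply(stats::setNames(tree$tip.label, tree$tip.label), function(sp) {
    g <- node_genomes[[sp]]
    hit <- g$gene_id %in% names(canon)
    stats::setNames(g$chrom[hit], unname(canon[g$gene_id[hit]]))
  })
  coloc <- do.call(rbind, lapply(tree$tip.label, function(sp) {
    p <- presence[[sp]]
    if (length(p) < 2) return(NULL)
    cmb <- utils::combn(sort(names(p)), 2)
    data.frame(lineage = sp, a = cmb[1, ], b = cmb[2, ],
               same_chrom = p[cmb[1, ]] == p[cmb[2, ]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(presence = presence, colocation = coloc,
                 node_genomes = node_genomes), class = "scenario_prediction")
}

#' Check a scenario prediction against observed repertoires
#'
#' @param predicted a `scenario_prediction` from [apply_scenario()].
#' @param observed list with `presence`: matrix/data.frame of "1"/"0"/"."
#'   (class rows x lineage columns; "." = unresolved/never evolved, not
#'   checked) and optional `colocate`: data.frame(lineage, a, b,
#'   same_chrom).
#' @return list(consistent, violations).
#' @export
scenario_consistent <- function(predicted, observed) {
  viol <- character()
  pm <- as.matrix(observed$presence)
  for (lin in colnames(pm)) {
    if (!lin %in% names(predicted$presence)) next
    have <- names(predicted$presence[[lin]])
    for (cls in rownames(pm)) {
      cell <- pm[cls, lin]
      if (cell == "1" && !cls %in% have)
        viol <- c(viol, sprintf("%s: missing %s", lin, cls))
      if (cell == "0" && cls %in% have)
        viol <- c(viol, sprintf("%s: unexpected %s", lin, cls))
    }
  }
  for (i in seq_len(nrow(observed$colocate %||% data.frame()))) {
    row <- observed$colocate[i, ]
    p <- predicted$presence[[row$lineage]]
    if (is.null(p) || !all(c(row$a, row$b) %in% names(p))) next
    same <- p[[row$a]] == p[[row$b]]
    want <- isTRUE(as.logical(row$same_chrom))
    if (same != want)
      viol <- c(viol, sprintf("%s: %s/%s %s co-located", row$lineage, row$a, row$b,
                              if (want) "not" else "unexpectedly"))
  }
  list(consistent = !length(viol), violations = viol)
}

#' Dollo gain/loss reconstruction for one gene on a species tree
#'
#' Places a single gain at the most recent common ancestor of all leaves
#' carrying the gene, then the minimal set of loss branches covering the
#' absent leaves below the gain (each loss is the branch above a maximal
#' subtree containing absences but no presence). Leaves coded `NA`
#' (unresolved / gene never evolved in that lineage) are unconstrained.
#'
#' @param tree rooted species tree (Newick or `phylo`).
#' @param presence named vector over leaves: 1/0/NA (or "1"/"0"/".").
#' @return list(gain = branch label, losses = character vector of branch
#'   labels).
#' @export
dollo_reconstruct <- function(tree, presence) {
  tree <- read_species_tree(tree)
  pv <- presence[tree$tip.label]
  pv <- ifelse(pv %in% c(1, "1"), 1L, ifelse(pv %in% c(0, "0"), 0L, NA_integer_))
  names(pv) <- tree$tip.label
  present <- names(pv)[!is.na(pv) & pv == 1L]
  if (!length(present)) stop("dollo_reconstruct: gene absent from every leaf")
  gain_node <- mrca_node(tree, present)
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  losses <- character()
  descend <- function(node) {
    leaves <- clade_leaves(tree, node)
    vals <- pv[leaves]
    if (any(!is.na(vals) & vals == 1L)) {
      if (node <= ntip) return(invisible())
      for (kid in tree_children(tree, node)) descend(kid)
    } else if (any(!is.na(vals) & vals == 0L)) {
      losses <<- c(losses, labels[node])   # maximal presence-free subtree
    }
  }
  descend(gain_node)
  list(gain = labels[gain_node], losses = sort(losses))
}

#' Minimal-step scenario search at gene-class granularity
#'
#' Exhaustive branch-and-bound over loss/duplication histories on a small
#' species tree: finds the cheapest event assignment whose replay matches
#' the observed per-leaf class repertoires. Kept at desk scale (the search
#' is exponential); leaf branches are solved in closed form (set
#' differences), internal branches by enumeration with a cost bound.
#'
#' @param tree rooted species tree.
#' @param ancestor_classes character vector of gene classes in the root
#'   ancestor.
#' @param observed named list leaf -> character vector of observed classes
#'   (or matrix of "1"/"0"/"." rows = classes, cols = leaves).
#' @param universe candidate class names duplications may create (default:
#'   all observed plus ancestral classes).
#' @param max_steps search bound (default 8, must be <= 12).
#' @param grammar named list branch label -> subset of c("loss", "dup")
#'   allowed there; default both everywhere.
#' @return list(count, events = data.frame(branch, kind, class, new_class))
#'   or NULL when nothing within the bound is consistent.
#' @export
min_steps_search <- function(tree, ancestor_classes, observed, universe = NULL,
                             max_steps = 8, grammar = NULL) {
  stopifnot(max_steps <= 12)
  tree <- read_species_tree(tree)
  if (is.matrix(observed) || is.data.frame(observed)) {
    m <- as.matrix(observed)
    observed <- lapply(stats::setNames(colnames(m), colnames(m)),
                       function(l) rownames(m)[m[, l] == "1"])
  }
  if (is.null(universe))
    universe <- sort(unique(c(ancestor_classes, unlist(observed))))
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  allowed <- function(lab) grammar[[lab]] %||% c("loss", "dup")
  no_events <- data.frame(branch = character(), kind = character(),
                          class = character(), new_class = character(),
                          stringsAsFactors = FALSE)
  # cheapest edit for a leaf edge is a closed form: one loss per class to
  # drop, one duplication per class to add (any surviving class can serve
  # as the duplication source)
  leaf_cost <- function(state, leaf) {
    obs <- observed[[leaf]] %||% character()
    losses <- setdiff(state, obs)
    gains <- setdiff(obs, state)
    if (length(losses) && !"loss" %in% allowed(leaf)) return(list(cost = Inf))
    if (length(gains) &&
        (!"dup" %in% allowed(leaf) || !length(setdiff(state, losses))))
      return(list(cost = Inf))
    evs <- rbind(
      if (length(losses)) data.frame(branch = leaf, kind = "loss", class = losses,
                                     new_class = NA_character_, stringsAsFactors = FALSE),
      if (length(gains)) data.frame(branch = leaf, kind = "dup",
                                    class = setdiff(state, losses)[1],
                                    new_class = gains, stringsAsFactors = FALSE))
    list(cost = length(losses) + length(gains), events = evs %||% no_events)
  }
  # all event sequences of cost <= budget on one internal branch, in
  # canonical (sorted-key) order so permutations are enumerated once
  branch_options <- function(state, budget, lab) {
    opts <- list(list(cost = 0, state = state, events = NULL, key = ""))
    frontier <- opts
    while (length(frontier)) {
      nxt <- list()
      for (o in frontier) {
        if (o$cost >= budget) next
        moves <- list()
        if ("loss" %in% allowed(lab))
          for (cl in o$state) moves[[length(moves) + 1]] <- c("loss", cl, NA)
        if ("dup" %in% allowed(lab))
          for (cl in o$state) for (nc in setdiff(universe, o$state))
            moves[[length(moves) + 1]] <- c("dup", cl, nc)
        for (mv in moves) {
          key <- paste(mv[1], mv[2], mv[3], sep = "\r")
          if (key < o$key) next
          st <- if (mv[1] == "loss") setdiff(o$state, mv[2]) else c(o$state, mv[3])
          ev <- data.frame(branch = lab, kind = mv[1], class = mv[2],
                           new_class = mv[3], stringsAsFactors = FALSE)
          cand <- list(cost = o$cost + 1, state = st,
                       events = rbind(o$events, ev), key = key)
          nxt[[length(nxt) + 1]] <- cand
          opts[[length(opts) + 1]] <- cand
        }
      }
      frontier <- nxt
    }
    opts
  }
  best <- NULL
  best_cost <- Inf
  # explore the subtree below `node` (whose class set is `state`) and call
  # `cont(events, budget_left)` for every feasible completion within budget
  explore <- function(node, state, budget, acc, cont) {
    kids <- tree_children(tree, node)
    step <- function(i, budget_left, acc2) {
      used <- if (is.null(acc2)) 0 else nrow(acc2)
      if (used >= best_cost) return(invisible())
      if (i > length(kids)) { cont(acc2, budget_left); return(invisible()) }
      kid <- kids[i]
      lab <- labels[kid]
      if (kid <= ntip) {
        lc <- leaf_cost(state, lab)
        if (!is.finite(lc$cost) || lc$cost > budget_left) return(invisible())
        step(i + 1, budget_left - lc$cost, rbind(acc2, lc$events))
      } else {
        for (o in branch_options(state, budget_left, lab)) {
          explore(kid, o$state, budget_left - o$cost, rbind(acc2, o$events),
                  function(acc3, b3) step(i + 1, b3, acc3))
        }
      }
    }
    step(1, budget, acc)
  }
  explore(root_node(tree), ancestor_classes, max_steps, NULL,
          function(acc, budget_left) {
            used <- if (is.null(acc)) 0 else nrow(acc)
            if (used < best_cost) { best_cost <<- used; best <<- acc }
          })
  if (!is.finite(best_cost)) return(NULL)
  list(count = as.integer(best_cost), events = best %||% no_events)
}
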