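# Small genome-table builders and brute-force oracles used across tests.

mini_table <- function(ids, species = "sp", chrom = "chr1", strand = "+",
                       family = ids, biotype = "protein_coding") {
  chrom <- rep(chrom, length.out = length(ids))
  oi <- stats::ave(seq_along(ids), chrom, FUN = seq_along) - 1L
  genome_table(data.frame(gene_id = ids, chrom = chrom, order_index = oi,
                          strand = strand, family = family, biotype = biotype,
                          stringsAsFactors = FALSE), species)
}

# ---- brute-force maximal collinear chains -------------------------------
# Enumerates every valid chain (all monotone subsequences under the gap
# rule), then keeps those not strictly contained in a longer valid chain.
oracle_chains <- function(pairs, min_pairs, max_gap) {
  n <- nrow(pairs)
  if (!n) return(character())
  found <- list()
  for (sgn in c(1L, -1L)) {
    edge <- function(i, j) {
      dr <- pairs$ref_index[j] - pairs$ref_index[i]
      dq <- sgn * (pairs$query_index[j] - pairs$query_index[i])
      dr > 0 && dr <= max_gap && dq > 0 && dq <= max_gap
    }
    grow <- function(path) {
      found[[length(found) + 1]] <<- list(idx = path, sgn = sgn)
      for (j in seq_len(n)) if (edge(path[length(path)], j)) grow(c(path, j))
    }
    for (i in seq_len(n)) grow(i)
  }
  keep <- vapply(seq_along(found), function(i) {
    a <- found[[i]]
    !any(vapply(seq_along(found), function(j) {
      b <- found[[j]]
      j != i && b$sgn == a$sgn && length(b$idx) > length(a$idx) &&
        all(a$idx %in% b$idx)
    }, logical(1)))
  }, logical(1))
  out <- found[keep]
  out <- out[vapply(out, function(ch) length(ch$idx) >= min_pairs, logical(1))]
  unique(vapply(out, function(ch)
    paste(ch$sgn, paste(ch$idx, collapse = ","), sep = ":"), character(1)))
}

chain_keys <- function(chains, pairs) {
  rowkey <- paste(pairs$ref_index, pairs$query_index)
  vapply(chains, function(ch) {
    idx <- match(paste(ch$pairs$ref_index, ch$pairs$query_index), rowkey)
    paste(if (ch$orientation == "colinear") 1L else -1L,
          paste(idx, collapse = ","), sep = ":")
  }, character(1))
}

random_pairs <- function(n, max_index = 24) {
  unique(data.frame(ref_index = sample(0:max_index, n, replace = TRUE),
                    query_index = sample(0:max_index, n, replace = TRUE)))
}

# ---- brute-force Dollo cost ---------------------------------------------
# Minimal number of loss branches over all single-gain labelings: for each
# candidate gain node, find the smallest set of below-gain branches whose
# "lost" subtrees reproduce the observed 1/0 pattern (NA unconstrained).
oracle_dollo_cost <- function(tree, presence) {
  tree <- paralogon::read_species_tree(tree)
  labels <- c(tree$tip.label, tree$node.label)
  pv <- presence[tree$tip.label]
  pv <- ifelse(pv %in% c(1, "1"), 1L, ifelse(pv %in% c(0, "0"), 0L, NA_integer_))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- function(node) {  # all nodes strictly below `node`
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[[1]]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      out <- c(out, kids); stack <- c(stack, kids[kids > ntip])
    }
    out
  }
  leaves_under <- function(node) {
    if (node <= ntip) return(node)
    setdiff(below(node), seq_len(nnode)[-seq_len(ntip)])
  }
  on_path_blocked <- function(leaf, gain, losses) {
    nd <- leaf
    while (nd != gain) {
      if (nd %in% losses) return(TRUE)
      nd <- tree$edge[tree$edge[, 2] == nd, 1]
      if (!length(nd)) return(FALSE)
    }
    FALSE
  }
  best <- Inf
  for (gain in seq_len(nnode)) {
    under <- leaves_under(gain)
    outside <- setdiff(seq_len(ntip), under)
    if (any(!is.na(pv[outside]) & pv[outside] == 1L)) next
    cand <- below(gain)
    for (k in 0:length(cand)) {
      if (k >= best) break
      combos <- if (k == 0) list(integer(0)) else
        utils::combn(cand, k, simplify = FALSE)
      ok <- FALSE
      for (S in combos) {
        good <- TRUE
        for (leaf in under) {
          if (is.na(pv[leaf])) next
          blocked <- on_path_blocked(leaf, gain, S)
          if ((pv[leaf] == 1L) == blocked) { good <- FALSE; break }
        }
        if (good) { ok <- TRUE; break }
      }
      if (ok) { best <- min(best, k); break }
    }
  }
  best
}

# ---- class-repertoire replay and exhaustive step-count oracle -----------
# Replays loss/dup class events down a tree of repertoires (independent of
# the package's genome-level replay).
replay_classes <- function(tree, ancestor, events) {
  tree <- paralogon::read_species_tree(tree)
  labels <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  state_of <- list()
  state_of[[labels[ntip + 1]]] <- ancestor
  ord <- c(ntip + 1L)
  repeat {
    nxt <- tree$edge[tree$edge[, 1] %in% ord & !tree$edge[, 2] %in% ord, 2]
    if (!length(nxt)) break
    for (nd in nxt) {
      par <- tree$edge[tree$edge[, 2] == nd, 1]
      st <- state_of[[labels[par]]]
      evs <- events[events$branch == labels[nd], , drop = FALSE]
      for (i in seq_len(nrow(evs))) {
        st <- if (evs$kind[i] == "loss") setdiff(st, evs$class[i])
              else union(st, evs$new_class[i])
      }
      state_of[[labels[nd]]] <- st
    }
    ord <- c(ord, nxt)
  }
  lapply(setNames(tree$tip.label, tree$tip.label), function(l) sort(state_of[[l]]))
}

# Iterative-deepening enumeration over valid loss/dup assignments: every
# branch (in preorder) receives an event sequence (losses of present
# classes, duplications into absent ones); leaves are compared against the
# observation. No closed forms, no best-cost pruning - pure enumeration.
oracle_min_steps <- function(tree, ancestor, observed, universe, bound = 6) {
  tr <- paralogon::read_species_tree(tree)
  labels <- c(tr$tip.label, tr$node.label)
  ntip <- length(tr$tip.label)
  kids_of <- function(node) tr$edge[tr$edge[, 1] == node, 2]
  exists_d <- function(d) {
    found <- FALSE
    # assign events to the branch above `node` given parent state, then
    # recurse into the node's children; spend at most `budget` in total
    branch_seqs <- function(state, budget) {
      acc <- list(list(state = state, cost = 0))
      frontier <- acc
      while (length(frontier)) {
        nxt <- list()
        for (o in frontier) {
          if (o$cost >= budget) next
          for (cl in o$state)
            nxt[[length(nxt) + 1]] <- list(state = setdiff(o$state, cl),
                                           cost = o$cost + 1)
          for (nc in setdiff(universe, o$state))
            nxt[[length(nxt) + 1]] <- list(state = c(o$state, nc),
                                           cost = o$cost + 1)
        }
        acc <- c(acc, nxt)
        frontier <- nxt
      }
      acc
    }
    descend <- function(node, state, budget, cont) {
      if (found) return(invisible())
      if (node <= ntip) {
        if (identical(sort(state), sort(observed[[labels[node]]])))
          cont(budget)
        return(invisible())
      }
      kids <- kids_of(node)
      step <- function(i, budget_left) {
        if (found) return(invisible())
        if (i > length(kids)) { cont(budget_left); return(invisible()) }
        for (o in branch_seqs(state, budget_left)) {
          descend(kids[i], o$state, budget_left - o$cost,
                  function(b) step(i + 1, b))
          if (found) return(invisible())
        }
      }
      step(1, budget)
    }
    descend(ntip + 1L, ancestor, d, function(b) { if (b == 0) found <<- TRUE })
    found
  }
  for (d in 0:bound) if (exists_d(d)) return(d)
  Inf
}
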