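#' Simulate gene-order evolution along a species tree
#'
#' Replays explicit per-branch event lists (and/or draws events from
#' per-branch Poisson rates) down a rooted species tree, starting from an
#' ancestral genome, and emits extant genomes together with ground-truth
#' homology families, locus (orthogroup) labels and the full event log.
#' Deterministic for a fixed `(config, seed)` pair.
#'
#' @param config list with elements:
#'   * `tree`: Newick string or `phylo` (rooted; node labels name branches),
#'   * `ancestor`: named list, chromosome -> ordered character vector of
#'     gene ids, or a [genome_table()],
#'   * `families`: optional named vector gene id -> family label (default:
#'     every ancestral gene founds its own family),
#'   * `root_events`: events applied to the ancestor before the first split,
#'   * `branch_events`: named list, branch label -> list of [event()]s,
#'   * `rates`: optional named numeric, event kind -> Poisson mean per
#'     branch, for randomly generated events (applied after any explicit
#'     events on the branch),
#'   * `locus_names`: optional named vector, locus id -> canonical
#'     orthogroup name, attached to the truth table.
#' @param seed integer seed; recorded in the dataset.
#' @return object of class `synthetic_dataset`: list(genomes, node_genomes,
#'   event_log, tree, truth, seed, config).
#' @export
simulate_evolution <- function(config, seed = 1L) {
  stopifnot(is.list(config), !is.null(config$tree), !is.null(config$ancestor))
  if (!is.null(config$rates) && any(config$rates < 0))
    stop("simulate_evolution: negative event rates")
  set.seed(as.integer(seed))
  tree <- read_species_tree(config$tree)
  anc <- if (inherits(config$ancestor, "genome_table")) config$ancestor
         else ancestor_table(config$ancestor, config$families)
  log <- list()
  root_state <- anc
  for (ev in config$root_events %||% list()) {
    root_state <- apply_event(root_state, ev)
    log[[length(log) + 1]] <- ev
  }
  labels <- node_labels(tree)
  node_genomes <- list()
  node_genomes[[labels[root_node(tree)]]] <- root_state
  for (node in setdiff(preorder_nodes(tree), root_node(tree))) {
    lab <- labels[node]
    state <- node_genomes[[labels[parent_node(tree, node)]]]
    for (ev in config$branch_events[[lab]] %||% list()) {
      ev$branch <- lab
      state <- apply_event(state, ev)
      log[[length(log) + 1]] <- ev
    }
    if (!is.null(config$rates)) {
      for (ev in draw_branch_events(state, config$rates, lab)) {
        state <- apply_event(state, ev)
        log[[length(log) + 1]] <- ev
      }
    }
    node_genomes[[lab]] <- state
  }
  genomes <- lapply(stats::setNames(tree$tip.label, tree$tip.label), function(sp) {
    g <- node_genomes[[sp]]
    g <- rebuild_table(stats::setNames(as.data.frame(g), names(g)), sp)
    attr(g, "te_marks") <- attr(node_genomes[[sp]], "te_marks")
    assign_coordinates(g)
  })
  truth <- do.call(rbind, lapply(tree$tip.label, function(sp) {
    g <- genomes[[sp]]
    data.frame(species = sp, gene_id = g$gene_id, chrom = g$chrom,
               family = g$family, locus = g$locus,
               canonical = unname((config$locus_names %||% character())[g$locus]),
               stringsAsFactors = FALSE)
  }))
  structure(list(genomes = genomes, node_genomes = node_genomes, event_log = log,
                 tree = tree, truth = truth, seed = as.integer(seed),
                 config = config),
            class = "synthetic_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$genomes), "species,",
      length(x$event_log), "events, seed", x$seed, "\n")
  invisible(x)
}

ancestor_table <- function(chrom_list, families = NULL) {
  genes <- do.call(rbind, lapply(names(chrom_list), function(ch) {
    ids <- chrom_list[[ch]]
    data.frame(gene_id = ids, chrom = ch, order_index = seq_along(ids) - 1L,
               strand = "+", stringsAsFactors = FALSE)
  }))
  genes$family <- genes$gene_id
  if (!is.null(families)) {
    hit <- genes$gene_id %in% names(families)
    genes$family[hit] <- unname(families[genes$gene_id[hit]])
  }
  genome_table(genes, "ancestor")
}

# Random per-branch events under Poisson rates; payloads drawn uniformly
# against the current genome state. Used by property tests.
draw_branch_events <- function(state, rates, branch) {
  out <- list()
  for (kind in names(rates)) {
    n <- stats::rpois(1, rates[[kind]])
    for (i in seq_len(n)) {
      ev <- draw_event(state, kind, branch)
      if (!is.null(ev)) {
        state <- apply_event(state, ev)
        out[[length(out) + 1]] <- ev
      }
    }
  }
  out
}

draw_event <- function(state, kind, branch) {
  genes <- as.data.frame(state)
  if (!nrow(genes)) return(NULL)
  chroms <- unique(genes$chrom)
  pick_range <- function(ch, maxlen) {
    n <- sum(genes$chrom == ch)
    if (n < 2) return(NULL)
    len <- sample(seq_len(min(maxlen, n - 1)), 1)
    from <- sample(0:(n - len), 1)
    c(from, from + len)
  }
  switch(kind,
    GENE_LOSS = event("GENE_LOSS", branch, gene = sample(genes$gene_id, 1)),
    TANDEM_DUP = event("TANDEM_DUP", branch, gene = sample(genes$gene_id, 1)),
    INVERSION = {
      ch <- sample(chroms, 1); r <- pick_range(ch, 8)
      if (is.null(r)) NULL else event("INVERSION", branch, chrom = ch, from = r[1], to = r[2])
    },
    SEG_DUP = {
      ch <- sample(chroms, 1); r <- pick_range(ch, 4)
      if (is.null(r)) NULL else {
        tgt <- sample(chroms, 1)
        event("SEG_DUP", branch, chrom = ch, from = r[1], to = r[2],
              target_chrom = tgt,
              target_after = sample(0:(sum(genes$chrom == tgt) - 1), 1) - 1L)
      }
    },
    TRANSLOCATION = {
      ch <- sample(chroms, 1); r <- pick_range(ch, 4)
      if (is.null(r) || length(chroms) < 2) NULL else {
        tgt <- sample(setdiff(chroms, ch), 1)
        event("TRANSLOCATION", branch, chrom = ch, from = r[1], to = r[2],
              target_chrom = tgt,
              target_after = sample(0:(sum(genes$chrom == tgt) - 1), 1) - 1L)
      }
    },
    WGD = event("WGD", branch),
    stop("draw_event: unsupported kind ", kind))
}

#' Ground-truth locus status matrix from a simulated dataset
#'
#' For every locus whose family is in `focus_families`, reports one status
#' per extant species: `present` (locus gene exists),
#' `gene_lost_territory_present` (gene deleted but at least `min_survive` of
#' its ancestral ten-gene neighbourhood co-occurs within a ten-gene span),
#' `territory_absent` (less survives), or `never_evolved` (the locus never
#' existed on that lineage's root-to-leaf path).
#'
#' @export
truth_orthogroups <- function(dataset, focus_families, min_survive = 0.5) {
  tree <- dataset$tree
  labels <- node_labels(tree)
  loci <- unique(unlist(lapply(dataset$node_genomes, function(g)
    g$locus[g$family %in% focus_families])))
  # a locus counts as present through WGD-derived descendants only: a WGD
  # suffixes both copies (/a, /b), "renaming" the locus, whereas tandem and
  # segmental copies (/t, /s) are new loci and leave the parent in place
  locus_present <- function(loci_vec, L) {
    rest <- substring(loci_vec[loci_vec == L | startsWith(loci_vec, paste0(L, "/"))],
                      nchar(L) + 1)
    any(rest == "" | grepl("^(/(a|b))+$", rest))
  }
  rows <- list()
  for (sp in tree$tip.label) {
    leaf <- dataset$genomes[[sp]]
    for (L in loci) {
      if (locus_present(leaf$locus, L)) {
        st <- "present"
      } else {
        node <- node_by_label(tree, sp)
        anc_window <- NULL
        repeat {
          node <- parent_node(tree, node)
          if (is.na(node)) break
          g <- dataset$node_genomes[[labels[node]]]
          rest <- substring(g$locus, nchar(L) + 1)
          hit <- which((g$locus == L | startsWith(g$locus, paste0(L, "/"))) &
                         (g$locus == L | grepl("^(/(a|b))+$", rest)))
          if (length(hit)) {
            nb <- neighbors(g, g$gene_id[hit[1]], k = 5)
            anc_window <- unique(c(gene_families(nb$upstream),
                                   gene_families(nb$downstream)))
            break
          }
        }
        st <- if (is.null(anc_window)) "never_evolved"
              else if (territory_survival(leaf, anc_window) >=
                       ceiling(length(anc_window) * min_survive))
                "gene_lost_territory_present" else "territory_absent"
      }
      rows[[length(rows) + 1]] <- data.frame(locus = L, species = sp, status = st,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ln <- dataset$config$locus_names
  out$canonical <- if (is.null(ln)) out$locus else
    ifelse(out$locus %in% names(ln), unname(ln[out$locus]), out$locus)
  out
}

# max number of distinct target families co-occurring in any 10-gene span
territory_survival <- function(table, target_families, span = 10) {
  fam <- gene_families(table)
  best <- 0L
  for (ch in unique(table$chrom)) {
    f <- fam[table$chrom == ch][order(table$order_index[table$chrom == ch])]
    n <- length(f)
    for (s in seq_len(max(1, n - span + 1))) {
      w <- f[s:min(n, s + span - 1)]
      best <- max(best, length(intersect(unique(w), target_families)))
    }
  }
  best
}

#' Packaged vertebrate receptor simulation config
#'
#' The generator's reference condition: the one-round-WGD + segmental-
#' duplication history of the six-member oxytocin/vasotocin receptor family,
#' played over a ten-lineage vertebrate tree (hagfish branching basally),
#' together with the OT/VT ligand tandem duplication. The ancestral genome
#' carries a single receptor (`VTR1`, later joined by the tandem `VTR2`
#' already present here as the pre-vertebrate segmental duplication) inside
#' zoned neighbourhoods; reciprocal neighbour losses after the WGD
#' differentiate the four post-WGD receptor territories, and two
#' translocated segmental duplications create `VTR1B` and `VTR2C` with
#' mostly-new territories. Lineage-specific losses reproduce the observed
#' presence/absence pattern, including the mammalian fission that split the
#' deleted-`VTR2A` territory across two chromosomes, the placental OT
#' inversion, and the teleost/holostean OT translocations.
#'
#' @return a config list for [simulate_evolution()].
#' @export
h1_receptor_config <- function() {
  pad <- function(p, n) sprintf("%s%02d", p, seq_len(n))
  chr1 <- c(pad("F", 6), pad("P", 10), "VTR1", pad("Q", 10), pad("G", 8),
            pad("R", 10), "VTR2", pad("S", 10), pad("H", 6))
  ancestor <- list(chr1 = chr1, chr2 = pad("K", 14), chr3 = pad("L", 14),
                   chrV = c(pad("V", 12), "VT", sprintf("V%02d", 13:24)))
  families <- c(VTR1 = "VTR", VTR2 = "VTR", VT = "VTLIG")
  tree <- paste0("(hagfishes,(lampreys,(sharks,((holostei,teleostei)neopterygii,",
                 "(coelacanth,(frogs,(mammals,(turtles_crocodiles,birds)",
                 "archosauria)amniota)tetrapoda)sarcopterygii)osteichthyes)",
                 "gnathostomata)vertebrata)craniata;")
  gl <- function(ids) lapply(ids, function(g) event("GENE_LOSS", gene = g))
  branch_events <- list(
    vertebrata = c(
      list(event("WGD"),
           # single-copy background chromosomes: the duplicate is lost outright
           event("SEGMENT_LOSS", chrom = "chr2_b", from = 0, to = 14),
           event("SEGMENT_LOSS", chrom = "chr3_b", from = 0, to = 14),
           event("SEGMENT_LOSS", chrom = "chrV_b", from = 0, to = 25)),
      # reciprocal near-zone losses differentiate the two receptor paralogons
      gl(paste0(pad("Q", 5), "_a")), gl(paste0(sprintf("S%02d", 1:5), "_a")),
      gl(paste0(sprintf("P%02d", 6:10), "_b")), gl(paste0(sprintf("R%02d", 6:10), "_b"))),
    gnathostomata = list(
      event("TANDEM_DUP", gene = "VT_a", copy_id = "OT", mark_te_flank = TRUE),
      event("SEG_DUP", chrom = "chr1_a", from = 15, to = 18,
            target_chrom = "chr2_a", target_after = 6,
            copy_ids = c("P10_sB", "VTR1B", "Q06_sB"))),
    osteichthyes = list(
      event("SEG_DUP", chrom = "chr1_b", from = 34, to = 37,
            target_chrom = "chr3_a", target_after = 5,
            copy_ids = c("R05_sC", "VTR2C", "S01_sC"))),
    lampreys = list(event("TANDEM_DUP", gene = "VTR1_b")),
    hagfishes = list(event("FISSION", chrom = "chr1", at = 31)),
    tetrapoda = list(event("GENE_LOSS", gene = "VTR2_b")),
    mammals = list(event("GENE_LOSS", gene = "VTR2_a"),
                   event("FISSION", chrom = "chr1_a", at = 40),
                   event("INVERSION", chrom = "chrV_a", from = 13, to = 14)),
    teleostei = list(event("GENE_LOSS", gene = "VTR2_a"),
                     event("TRANSLOCATION", chrom = "chrV_a", from = 13, to = 14,
                           target_chrom = "chrV_a", target_after = 20)),
    holostei = list(event("TRANSLOCATION", chrom = "chrV_a", from = 12, to = 14,
                          target_chrom = "chrV_a", target_after = 20),
                    event("INVERSION", chrom = "chrV_a", from = 20, to = 21)),
    birds = list(event("GENE_LOSS", gene = "VTR2C")),
    neopterygii = list(event("GENE_LOSS", gene = "VTR1B")))
  locus_names <- c("VTR1" = "VTR1", "VTR2" = "VTR2",
                   "VTR1/a" = "VTR1A", "VTR1/b" = "OTR", "VTR1/b/t1" = "OTR",
                   "VTR1/a/s1" = "VTR1B", "VTR2/a" = "VTR2A", "VTR2/b" = "VTR2B",
                   "VTR2/b/s1" = "VTR2C",
                   "VT" = "VT", "VT/a" = "VT", "VT/a/t1" = "OT")
  list(tree = tree, ancestor = ancestor, families = families,
       branch_events = branch_events, locus_names = locus_names,
       receptor_family = "VTR", ligand_family = "VTLIG")
}
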