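#' Packaged vertebrate species tree
#'
#' Ten lineage groups; hagfishes branch before lampreys (the two-receptor
#' hagfish repertoire favours cyclostome paraphyly under the one-round-WGD
#' history; the hagfish/lamprey relationship is otherwise treated as
#' unresolved). Internal nodes are labelled with clade names used as branch
#' ids everywhere (vertebrata, gnathostomata, osteichthyes, neopterygii,
#' sarcopterygii, tetrapoda, amniota, archosauria).
#' @export
species_tree_fixture <- function() {
  read_species_tree(system.file("extdata", "species_tree.nwk", package = "paralogon"))
}

#' Encoded presence/absence matrix of the OT/VT ligand and receptor genes
#'
#' Rows: gene classes; columns: the ten lineage groups; entries "1"
#' (present), "0" (lost) or "." (never evolved there / unresolved). The
#' hagfish column records the two ancestral-type receptors (VTR1, VTR2)
#' and leaves the six within-subfamily orthogroups unresolved.
#' @export
presence_matrix_fixture <- function() {
  read_presence_matrix(system.file("extdata", "presence_matrix.tsv",
                                   package = "paralogon"))
}

#' @rdname presence_matrix_fixture
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!all(m %in% c("1", "0", "."))) stop("presence matrix entries must be 1/0/.")
  m
}

#' Observed receptor repertoires with chromosome co-location constraints
#'
#' The observation the duplication scenarios are scored against: receptor
#' presence/absence per lineage plus the two recurring same-chromosome
#' pairs (OTR with VTR2B; VTR1A with VTR2A) in the lineages that retain
#' both.
#' @export
receptor_observation <- function() {
  m <- presence_matrix_fixture()
  receptors <- c("OTR", "VTR1A", "VTR1B", "VTR2A", "VTR2B", "VTR2C", "VTR1", "VTR2")
  coloc <- utils::read.table(system.file("extdata", "colocations.tsv",
                                         package = "paralogon"),
                             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  list(presence = m[intersect(receptors, rownames(m)), , drop = FALSE],
       colocate = coloc)
}

receptor_scenario_base <- function() {
  list(ancestor = list(chrM = c("m1", "VTR", "m2", "m3"),
                       chrN = c("n1", "n2"), chrP = c("p1", "p2")),
       tree = species_tree_fixture())
}

#' Hypothesis-1 scenario: one WGD plus segmental duplications
#'
#' The compact gene-class encoding of the one-round-WGD history: a tandem
#' segmental duplication of the single ancestral receptor (VTR -> VTR1 +
#' VTR2) before the hagfish divergence; one whole-genome duplication on the
#' vertebrate stem (shared by lampreys), yielding the VTR1A-VTR2A and
#' OTR-VTR2B chromosome pairs; a translocated segmental duplication of the
#' VTR1A region on the jawed-vertebrate stem (-> VTR1B); and a translocated
#' segmental duplication of the VTR2B region on the bony-vertebrate stem
#' (-> VTR2C). Under the unit-cost model this costs 6 steps
#' (1 + 1 + 2 + 2).
#' @export
scenario_h1 <- function() {
  base <- receptor_scenario_base()
  evs <- list(
    event("TANDEM_DUP", gene = "VTR", copy_id = "VTRII"),
    event("WGD", branch = "vertebrata"),
    event("SEG_DUP", branch = "gnathostomata", chrom = "chrM_a", from = 1, to = 2,
          target_chrom = "chrN_a", target_after = 0, copy_ids = "VTR1B"),
    event("SEG_DUP", branch = "osteichthyes", chrom = "chrM_b", from = 2, to = 3,
          target_chrom = "chrP_a", target_after = 0, copy_ids = "VTR2C"))
  canonical <- c(VTR = "VTR1", VTRII = "VTR2",
                 VTR_a = "VTR1A", VTR_b = "OTR",
                 VTRII_a = "VTR2A", VTRII_b = "VTR2B",
                 VTR1B = "VTR1B", VTR2C = "VTR2C")
  scenario(base$tree, base$ancestor, evs, canonical)
}

#' Hypothesis-2 scenario: two rounds of whole-genome duplication
#'
#' The compact encoding of the two-round-WGD history: the same initial
#' tandem duplication, then two WGDs on the vertebrate stem producing eight
#' receptors on four chromosome pairs. Matching the observed six-receptor
#' repertoire then requires losing the never-observed VTR1C and VTR2D on
#' the jawed-vertebrate stem and losing the VTR1B/VTR2C/VTR1C/VTR2D classes
#' on the lamprey stem: 9 steps (1 + 1 + 1 + 2 + 4). The hagfish lineage is
#' left unresolved under this hypothesis.
#' @export
scenario_h2 <- function() {
  base <- receptor_scenario_base()
  evs <- list(
    event("TANDEM_DUP", gene = "VTR", copy_id = "VTRII"),
    event("WGD", branch = "vertebrata"),
    event("WGD", branch = "vertebrata"),
    event("GENE_LOSS", branch = "gnathostomata", gene = "VTR_b_b"),
    event("GENE_LOSS", branch = "gnathostomata", gene = "VTRII_a_b"),
    event("GENE_LOSS", branch = "lampreys", gene = "VTR_a_b"),
    event("GENE_LOSS", branch = "lampreys", gene = "VTRII_b_b"),
    event("GENE_LOSS", branch = "lampreys", gene = "VTR_b_b"),
    event("GENE_LOSS", branch = "lampreys", gene = "VTRII_a_b"))
  canonical <- c(VTR = "VTR1", VTRII = "VTR2",
                 VTR_a_a = "VTR1A", VTRII_a_a = "VTR2A",
                 VTR_b_a = "OTR", VTRII_b_a = "VTR2B",
                 VTR_a_b = "VTR1B", VTRII_a_b = "VTR2D",
                 VTR_b_b = "VTR1C", VTRII_b_b = "VTR2C")
  scenario(base$tree, base$ancestor, evs, canonical)
}

#' Shared lineage-specific receptor losses
#'
#' The five downstream losses both hypotheses agree on (VTR2B on the
#' tetrapod stem; VTR2A independently in mammals and teleosts; VTR1B on the
#' holostei+teleostei stem; VTR2C in birds), appended to a scenario so its
#' replay matches the extant repertoires. Gene ids are resolved through the
#' scenario's canonical map, so the same table serves both encodings.
#' @export
append_lineage_losses <- function(scn) {
  losses <- data.frame(
    branch = c("tetrapoda", "mammals", "teleostei", "neopterygii", "birds"),
    class = c("VTR2B", "VTR2A", "VTR2A", "VTR1B", "VTR2C"),
    stringsAsFactors = FALSE)
  inverse <- stats::setNames(names(scn$canonical), scn$canonical)
  evs <- lapply(seq_len(nrow(losses)), function(i)
    event("GENE_LOSS", branch = losses$branch[i],
          gene = unname(inverse[losses$class[i]])))
  scenario(scn$tree, scn$ancestor, c(scn$events, evs), scn$canonical)
}

#' Synthetic gene-tree fixture with discordant lamprey placements
#'
#' A gene-family tree (with bootstrap percentages as node labels) in which
#' the lamprey OTR/VTR1A and VTR2A/VTR2B sequences cluster as
#' lineage-internal pairs outside their synteny-defined orthogroups - the
#' topology/synteny contradiction pattern - rooted on three amphioxus VTR
#' sequences.
#' @return list(tree, map = data.frame(leaf, species, orthogroup)).
#' @export
gene_tree_fixture <- function() {
  nwk <- system.file("extdata", "gene_tree_synthetic.nwk", package = "paralogon")
  tree <- read_gene_tree(nwk, outgroup = c("amphioxus_VTRx1", "amphioxus_VTRx2",
                                           "amphioxus_VTRx3"))
  map <- utils::read.table(system.file("extdata", "gene_tree_map.tsv",
                                       package = "paralogon"),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  list(tree = tree, map = map)
}

#' Synthetic alignment with planted subfamily-diagnostic columns
#'
#' Builds an amino-acid alignment of two sequence groups with exactly
#' `n_diag` columns fixed within each group and different between groups;
#' all other columns are guaranteed non-diagnostic (both groups share a
#' residue, or a group is polymorphic). Deterministic for a fixed seed.
#'
#' @param n_per_group sequences per group.
#' @param n_cols alignment length.
#' @param n_diag number of planted diagnostic columns.
#' @param seed RNG seed.
#' @return list(alignment, group_a, group_b, diagnostic_columns).
#' @export
make_diagnostic_alignment <- function(n_per_group = 4, n_cols = 60, n_diag = 9,
                                      seed = 1) {
  stopifnot(n_diag <= n_cols)
  set.seed(seed)
  res <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  diag_cols <- sort(sample(n_cols, n_diag))
  a <- matrix("", n_per_group, n_cols)
  b <- matrix("", n_per_group, n_cols)
  for (j in seq_len(n_cols)) {
    if (j %in% diag_cols) {
      rr <- sample(res, 2)
      a[, j] <- rr[1]; b[, j] <- rr[2]
    } else if (stats::runif(1) < 0.5) {
      a[, j] <- b[, j] <- sample(res, 1)       # conserved everywhere
    } else {
      shared <- sample(res, 1)                 # polymorphic, groups overlap
      other <- sample(setdiff(res, shared), 2)
      a[, j] <- sample(c(shared, other[1]), n_per_group, replace = TRUE)
      b[, j] <- sample(c(shared, other[2]), n_per_group, replace = TRUE)
      a[sample(n_per_group, 1), j] <- shared
      b[sample(n_per_group, 1), j] <- shared
    }
  }
  aln <- c(stats::setNames(apply(a, 1, paste, collapse = ""),
                           paste0("groupA_seq", seq_len(n_per_group))),
           stats::setNames(apply(b, 1, paste, collapse = ""),
                           paste0("groupB_seq", seq_len(n_per_group))))
  list(alignment = aln,
       group_a = paste0("groupA_seq", seq_len(n_per_group)),
       group_b = paste0("groupB_seq", seq_len(n_per_group)),
       diagnostic_columns = diag_cols)
}
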