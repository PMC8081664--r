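test_that("WGD doubles every chromosome and gene deterministically", {
  g <- genome_table(data.frame(
    gene_id = c(paste0("a", 1:7), paste0("b", 1:4)),
    chrom = rep(c("c1", "c2"), c(7, 4)), strand = "+"), "anc")
  out <- apply_event(g, event("WGD"))
  expect_equal(nrow(out), 22)
  expect_setequal(unique(out$chrom), c("c1_a", "c1_b", "c2_a", "c2_b"))
  expect_true(all(c("a1_a", "a1_b") %in% out$gene_id))
})

test_that("inversion reverses order and flips strands in the range", {
  g <- mini_table(paste0("g", 0:6))
  out <- apply_event(g, event("INVERSION", chrom = "chr1", from = 2, to = 5))
  expect_equal(out$gene_id[order(out$order_index)],
               c("g0", "g1", "g4", "g3", "g2", "g5", "g6"))
  expect_equal(out$strand[match(c("g2", "g3", "g4"), out$gene_id)],
               c("-", "-", "-"))
  expect_equal(out$strand[out$gene_id == "g0"], "+")
})

test_that("tandem duplication plus copy inversion makes a tail-to-tail pair", {
  g <- mini_table(paste0("g", 0:8))
  out <- apply_event(g, event("TANDEM_DUP", gene = "g4", copy_id = "g4copy"))
  i <- out$order_index[out$gene_id == "g4"]
  expect_equal(out$gene_id[out$order_index == i + 1], "g4copy")
  expect_equal(out$strand[out$gene_id == "g4copy"], "+")  # tail-to-head default
  out2 <- apply_event(out, event("INVERSION", chrom = "chr1", from = i + 1, to = i + 2))
  po <- pair_orientation(out2, "g4", "g4copy")
  expect_equal(po$class, "tail_to_tail")
  expect_equal(po$inverted, "g4copy")
})

test_that("segment loss, fission and translocation keep the order invariant", {
  g <- mini_table(paste0("g", 0:9))
  lost <- apply_event(g, event("SEGMENT_LOSS", chrom = "chr1", from = 3, to = 6))
  expect_equal(nrow(lost), 7)
  expect_equal(sort(lost$order_index), 0:6)
  fis <- apply_event(g, event("FISSION", chrom = "chr1", at = 4))
  expect_setequal(unique(fis$chrom), c("chr1_p1", "chr1_p2"))
  expect_equal(sum(fis$chrom == "chr1_p1"), 4)
  expect_equal(sort(fis$order_index[fis$chrom == "chr1_p2"]), 0:5)
  tr <- apply_event(fis, event("TRANSLOCATION", chrom = "chr1_p1", from = 0, to = 2,
                               target_chrom = "chr1_p2", target_after = 1))
  expect_equal(sum(tr$chrom == "chr1_p1"), 2)
  p2 <- tr[tr$chrom == "chr1_p2", ]
  expect_equal(p2$gene_id[order(p2$order_index)],
               c("g4", "g5", "g0", "g1", "g6", "g7", "g8", "g9"))
})

test_that("events with unresolvable payloads name the event", {
  g <- mini_table(paste0("g", 0:3))
  expect_error(apply_event(g, event("GENE_LOSS", gene = "nope")), "GENE_LOSS")
  expect_error(apply_event(g, event("INVERSION", chrom = "chr1", from = 2, to = 9)),
               "out of range")
  expect_error(apply_event(g, event("FISSION", chrom = "chrX", at = 1)), "chrX")
})

test_that("gene-count bookkeeping matches each event's arithmetic", {
  set.seed(7)
  g <- genome_table(data.frame(
    gene_id = paste0("g", 1:30), chrom = rep(c("c1", "c2"), each = 15),
    strand = "+"), "anc")
  evs <- list(event("TANDEM_DUP", gene = "g3"),
              event("SEG_DUP", chrom = "c1", from = 2, to = 6,
                    target_chrom = "c2", target_after = 3),
              event("SEGMENT_LOSS", chrom = "c2", from = 1, to = 4),
              event("GENE_LOSS", gene = "g20"),
              event("WGD"))
  delta <- c(1, 4, -3, -1, NA)
  n <- nrow(g)
  for (i in seq_along(evs)) {
    g <- apply_event(g, evs[[i]])
    n <- if (evs[[i]]$kind == "WGD") n * 2 else n + delta[i]
    expect_equal(nrow(g), n)
    expect_true(all(vapply(split(g$order_index, g$chrom), function(ix)
      identical(sort(ix), seq_along(ix) - 1L), logical(1))))
  }
})

test_that("zero events reproduce the ancestor at every leaf", {
  cfg <- list(tree = "((A,B)ab,C)r;",
              ancestor = list(c1 = paste0("g", 1:8)))
  ds <- simulate_evolution(cfg, seed = 5)
  for (sp in c("A", "B", "C"))
    expect_equal(ds$genomes[[sp]]$gene_id, paste0("g", 1:8))
  expect_equal(unique(ds$truth$locus), paste0("g", 1:8))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- list(tree = "((A,B)ab,C)r;",
              ancestor = list(c1 = paste0("g", 1:12), c2 = paste0("h", 1:8)),
              rates = c(GENE_LOSS = 2, TANDEM_DUP = 1, INVERSION = 1))
  d1 <- simulate_evolution(cfg, seed = 11)
  d2 <- simulate_evolution(cfg, seed = 11)
  for (sp in c("A", "B", "C"))
    expect_identical(as.data.frame(d1$genomes[[sp]]), as.data.frame(d2$genomes[[sp]]))
  expect_identical(length(d1$event_log), length(d2$event_log))
  d3 <- simulate_evolution(cfg, seed = 12)
  expect_false(identical(d1$event_log, d3$event_log))
})

test_that("replaying the emitted event log reproduces each leaf genome", {
  cfg <- list(tree = "((A,B)ab,C)r;",
              ancestor = list(c1 = paste0("g", 1:12), c2 = paste0("h", 1:8)),
              rates = c(GENE_LOSS = 2, TANDEM_DUP = 1, INVERSION = 1, SEG_DUP = 0.5))
  ds <- simulate_evolution(cfg, seed = 3)
  tree <- ds$tree
  anc <- ds$node_genomes[["r"]]
  # fold apply_event over the per-branch log along each root-to-leaf path
  path_to <- function(leaf) {
    labs <- c(tree$tip.label, tree$node.label)
    nd <- match(leaf, labs); path <- character()
    while (!is.na(nd) && nd != length(tree$tip.label) + 1) {
      path <- c(labs[nd], path)
      nd <- tree$edge[tree$edge[, 2] == nd, 1]
    }
    path
  }
  for (leaf in tree$tip.label) {
    st <- anc
    for (lab in path_to(leaf))
      for (ev in ds$event_log)
        if (!is.na(ev$branch) && ev$branch == lab) st <- apply_event(st, ev)
    got <- ds$genomes[[leaf]]
    expect_equal(st$gene_id, got$gene_id, info = leaf)
    expect_equal(st$chrom, got$chrom, info = leaf)
    expect_equal(st$order_index, got$order_index, info = leaf)
  }
})

test_that("packaged receptor config reproduces the encoded presence pattern", {
  ds <- simulate_evolution(h1_receptor_config(), seed = 1)
  m <- presence_matrix_fixture()
  tr <- ds$truth
  for (lin in colnames(m)) {
    have <- tr$canonical[tr$species == lin & !is.na(tr$canonical)]
    for (cls in c("OTR", "VTR1A", "VTR1B", "VTR2A", "VTR2B", "VTR2C", "OT", "VT",
                  "VTR1", "VTR2")) {
      cell <- m[cls, lin]
      if (cell == "1") expect_true(cls %in% have, label = paste(lin, cls, "present"))
      if (cell == "0") expect_false(cls %in% have, label = paste(lin, cls, "absent"))
    }
  }
})

test_that("ground-truth statuses distinguish loss, territory loss and absence", {
  ds <- simulate_evolution(h1_receptor_config(), seed = 1)
  tr <- truth_orthogroups(ds, "VTR")
  st <- function(cls, sp) tr$status[tr$canonical == cls & tr$species == sp]
  expect_equal(st("VTR2A", "mammals"), "gene_lost_territory_present")
  expect_equal(st("VTR2B", "frogs"), "gene_lost_territory_present")
  expect_equal(st("VTR1B", "lampreys"), "never_evolved")
  expect_equal(st("VTR2C", "sharks"), "never_evolved")
  expect_equal(st("VTR2C", "birds"), "gene_lost_territory_present")
  # lampreys carry two OTR-group loci (the original and the tandem copy)
  expect_true(all(st("OTR", "lampreys") == "present"))
  # a segment loss spanning the focus and its whole territory
  cfg <- list(tree = "((A,B)ab,C)r;",
              ancestor = list(c1 = paste0("g", 1:15)),
              branch_events = list(
                A = list(event("SEGMENT_LOSS", chrom = "c1", from = 1, to = 14))))
  ds2 <- simulate_evolution(cfg, seed = 1)
  tr2 <- truth_orthogroups(ds2, "g8")
  expect_equal(tr2$status[tr2$species == "A"], "territory_absent")
  expect_equal(tr2$status[tr2$species == "B"], "present")
})

test_that("TE-TIR markers follow the tandem copy and surface as repeats", {
  g <- assign_coordinates(apply_event(mini_table(paste0("g", 0:9)),
                                      event("TANDEM_DUP", gene = "g4",
                                            copy_id = "g4c", mark_te_flank = TRUE)))
  reps <- te_repeat_track(g)
  expect_equal(nrow(reps), 1)
  expect_true(reps$has_tir)
  hits_copy <- te_flank_scan(g, "g4c", reps, window_bp = 2000)
  expect_equal(nrow(hits_copy), 1)
  hits_src <- te_flank_scan(g, "g0", reps, window_bp = 2000)
  expect_equal(nrow(hits_src), 0)
})
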