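test_that("monophyletic orthogroups pass; grafted leaves are identified", {
  nwk <- "(((s1_X,s2_X)90,(s1_Y,s2_Y)85)95,out);"
  tree <- read_gene_tree(nwk, outgroup = "out")
  map <- data.frame(leaf = c("s1_X", "s2_X", "s1_Y", "s2_Y"),
                    species = c("s1", "s2", "s1", "s2"),
                    orthogroup = c("X", "X", "Y", "Y"))
  res <- orthogroup_monophyly(tree, map, low_support = 50) |>
    suppressWarnings()
  expect_true(all(res$monophyletic))
  expect_equal(res$violators, c("", ""))
  # graft one extra X leaf inside the Y clade
  nwk2 <- "(((s1_X,s2_X)90,((s1_Y,s3_X)40,s2_Y)85)95,out);"
  tree2 <- read_gene_tree(nwk2, outgroup = "out")
  map2 <- rbind(map, data.frame(leaf = "s3_X", species = "s3", orthogroup = "X"))
  res2 <- suppressWarnings(orthogroup_monophyly(tree2, map2))
  expect_false(res2$monophyletic[res2$orthogroup == "X"])
  expect_equal(res2$violators[res2$orthogroup == "X"], "s3_X")
  # the graft breaks Y too; removing the same grafted leaf restores it
  expect_false(res2$monophyletic[res2$orthogroup == "Y"])
  expect_equal(res2$violators[res2$orthogroup == "Y"], "s3_X")
})

test_that("the packaged discordant tree reports the lamprey placements", {
  gt <- gene_tree_fixture()
  res <- suppressWarnings(orthogroup_monophyly(gt$tree, gt$map))
  bad <- res[!res$monophyletic, ]
  expect_setequal(unlist(strsplit(bad$violators, ";")),
                  c("lamprey_OTR", "lamprey_VTR1A", "lamprey_VTR2A", "lamprey_VTR2B"))
  ok <- res[res$monophyletic, ]
  expect_true(all(c("VTR1B", "VTR2C") %in% ok$orthogroup))
})

test_that("monophyly agrees with brute-force clade enumeration on small trees", {
  set.seed(29)
  for (case in 1:15) {
    ntips <- sample(6:12, 1)
    tr <- ape::rtree(ntips, br = NULL)
    tr$tip.label <- paste0("t", seq_len(ntips))
    k <- sample(2:4, 1)
    groups <- sample(paste0("G", seq_len(k)), ntips, replace = TRUE)
    map <- data.frame(leaf = tr$tip.label, species = tr$tip.label,
                      orthogroup = groups)
    res <- suppressWarnings(orthogroup_monophyly(tr, map))
    for (g in unique(groups)) {
      leaves <- tr$tip.label[groups == g]
      if (length(leaves) < 2) next
      # brute force: some internal node's leaf set equals the group
      is_clade <- any(vapply((ntips + 1):(ntips + tr$Nnode), function(nd) {
        setequal(ape::extract.clade(tr, nd)$tip.label, leaves)
      }, logical(1))) || length(leaves) == ntips
      expect_equal(res$monophyletic[res$orthogroup == g], is_clade,
                   info = paste("case", case, "group", g))
    }
  }
})

test_that("diagnostic sites equal the per-column definition", {
  aln <- c(a1 = "AC", a2 = "AC", b1 = "AG", b2 = "AG")
  d <- diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$column, 2)
  expect_equal(d$residue_a, "C")
  expect_equal(d$residue_b, "G")
  # identical groups diagnose nothing
  expect_equal(nrow(diagnostic_sites(aln, c("a1", "a2"), c("a1", "a2"))), 0)
  expect_error(diagnostic_sites(c(x = "AC", y = "ACG"), "x", "y"), "ragged")
  # gapped columns are excluded by default
  aln2 <- c(a1 = "A-C", a2 = "AGC", b1 = "A-T", b2 = "AGT")
  d2 <- diagnostic_sites(aln2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d2$column, 3)
})

test_that("planted diagnostic columns are recovered exactly", {
  for (seed in c(1, 7, 19)) {
    fx <- make_diagnostic_alignment(n_per_group = 5, n_cols = 50, n_diag = 4,
                                    seed = seed)
    d <- diagnostic_sites(fx$alignment, fx$group_a, fx$group_b)
    expect_equal(d$column, fx$diagnostic_columns, info = paste("seed", seed))
  }
  # brute-force check on one instance
  fx <- make_diagnostic_alignment(seed = 3)
  m <- do.call(rbind, strsplit(fx$alignment, ""))
  brute <- which(vapply(seq_len(ncol(m)), function(j) {
    A <- unique(m[1:4, j]); B <- unique(m[5:8, j])
    length(A) == 1 && length(B) == 1 && A != B
  }, logical(1)))
  expect_equal(diagnostic_sites(fx$alignment, fx$group_a, fx$group_b)$column,
               brute)
})

test_that("universal renaming maps aliases, passes unknowns, and is idempotent", {
  al <- load_alias_table()
  r1 <- rename_genes(c("AVPR1A", "OXTR", "AVP", "MYSTERY9"), "mammals", al)
  expect_equal(r1$renamed, c("VTR1A", "OTR", "VT", "MYSTERY9"))
  expect_equal(r1$report$status,
               c("renamed", "renamed", "renamed", "unmatched"))
  r2 <- rename_genes("ITR", "fish", al)
  expect_equal(r2$renamed, "OTR")
  # already-universal names survive unchanged (idempotence)
  r3 <- rename_genes(r1$renamed, "mammals", al)
  expect_equal(r3$renamed, r1$renamed)
  expect_equal(rename_genes("VTR2C", "birds", al)$renamed, "VTR2C")
  # each alias maps back from its universal name within the lineage
  sub <- al[al$lineage == "birds", ]
  expect_true(all(rename_genes(sub$alias, "birds", al)$renamed == sub$universal))
})

test_that("alias tables with conflicting mappings are rejected at load", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("lineage\talias\tuniversal",
               "birds\tVT1\tVTR2A",
               "birds\tVT1\tVTR1B"), f)
  expect_error(load_alias_table(f), "conflicting")
  writeLines(c("lineage\talias\tuniversal",
               "birds\tVT1\tNOTAGENE"), f)
  expect_error(load_alias_table(f), "unknown universal")
})

test_that("the pipeline validates its config before running and summarises", {
  expect_error(run_pipeline(list(stages = "frobnicate")), "unknown stage")
  expect_error(run_pipeline(list(stages = "microsynteny")), "simulate")
  out <- withr::local_tempdir()
  res <- suppressWarnings(run_pipeline(list(stages = c("scenarios", "rename"),
                                            seed = 1, out_dir = out)))
  expect_equal(res$summary$h1_steps, 6)
  expect_equal(res$summary$h2_steps, 9)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "dollo_placements.tsv")))
  expect_true(res$scenarios$h1_consistent$consistent)
})
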