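test_that("window profiles list nearest families first and truncate at ends", {
  tb <- mini_table(paste0("g", 1:11), family = paste0("F", 1:11))
  p <- window_profile(tb, "g6", k = 5)
  expect_equal(p$upstream, paste0("F", 5:1))
  expect_equal(p$downstream, paste0("F", 7:11))
  p2 <- window_profile(tb, "g3", k = 5)
  expect_equal(p2$upstream, c("F2", "F1"))
  expect_error(window_profile(tb, "zz"), "unknown gene")
})

test_that("unlabelled neighbours become anonymous singletons", {
  tb <- mini_table(paste0("g", 1:5), family = c("F1", NA, "F3", NA, "F5"))
  p <- window_profile(tb, "g3", k = 2)
  expect_equal(p$upstream, c("anon:g2", "F1"))
  expect_equal(p$downstream, c("anon:g4", "F5"))
  q <- window_profile(mini_table(paste0("h", 1:5), family = c("F1", NA, "F3", NA, "F5")),
                      "h3", k = 2)
  expect_equal(shared_synteny_score(p, q)$count, 2)  # anons never match
})

test_that("shared synteny scores count distinct common families", {
  tb1 <- mini_table(paste0("a", 1:11), family = paste0("F", 1:11))
  tb2 <- mini_table(paste0("b", 1:11), family = paste0("F", 1:11))
  p1 <- window_profile(tb1, "a6"); p2 <- window_profile(tb2, "b6")
  s <- shared_synteny_score(p1, p2)
  expect_equal(s$count, 10)
  expect_equal(s$lcs, 10)
  tb3 <- mini_table(paste0("c", 1:11), family = paste0("X", 1:11))
  p3 <- window_profile(tb3, "c6")
  expect_equal(shared_synteny_score(p1, p3)$count, 0)
  tb4 <- mini_table(paste0("d", 1:11),
                    family = c("F2", "Y2", "Y3", "F7", "Y5", "d6",
                               "Y7", "F9", "Y9", "Y10", "Y11"))
  p4 <- window_profile(tb4, "d6")
  s4 <- shared_synteny_score(p1, p4)
  expect_equal(s4$count, 3)
  expect_equal(s4$matched, c("F2", "F7", "F9"))
  # symmetry and bound
  expect_equal(shared_synteny_score(p4, p1)$count, s4$count)
  expect_lte(s4$count, 2 * 5)
})

test_that("orthogroup assignment groups conserved loci across species", {
  cfg <- h1_receptor_config()
  ds <- simulate_evolution(cfg, seed = 2)
  cand <- do.call(rbind, lapply(names(ds$genomes), function(sp) {
    g <- ds$genomes[[sp]]
    data.frame(species = sp, gene_id = g$gene_id[g$family == "VTR"],
               stringsAsFactors = FALSE)
  }))
  calls <- assign_orthogroups(ds$genomes, cand)
  expect_equal(count_orthogroups(calls), 6)
  # every multi-species group is pure: all members share one truth locus class
  tr <- ds$truth
  key <- paste(tr$species, tr$gene_id)
  for (og in unique(calls$orthogroup)) {
    sub <- calls[calls$orthogroup == og, ]
    if (length(unique(sub$species)) < 2) next
    canon <- tr$canonical[match(paste(sub$species, sub$gene_id), key)]
    canon <- canon[!sub$species %in% "hagfishes"]  # ancestral-type genes are unresolvable
    expect_length(unique(canon), 1)
  }
  expect_error(assign_orthogroups(ds$genomes, cand[0, ]), "empty candidate")
})

test_that("assignment is invariant to species input order", {
  cfg <- h1_receptor_config()
  ds <- simulate_evolution(cfg, seed = 2)
  cand <- do.call(rbind, lapply(names(ds$genomes), function(sp) {
    g <- ds$genomes[[sp]]
    data.frame(species = sp, gene_id = g$gene_id[g$family == "VTR"],
               stringsAsFactors = FALSE)
  }))
  a <- assign_orthogroups(ds$genomes, cand)
  set.seed(9)
  perm <- sample(nrow(cand))
  b <- assign_orthogroups(rev(ds$genomes), cand[perm, ])
  norm <- function(x) {
    sets <- lapply(split(paste(x$species, x$gene_id), x$orthogroup), sort)
    sets[order(vapply(sets, `[`, character(1), 1))]
  }
  expect_equal(norm(a), norm(b))
})

test_that("lineage-specific tandem duplicates get a/b suffixes by synteny", {
  ds <- simulate_evolution(h1_receptor_config(), seed = 2)
  cand <- do.call(rbind, lapply(names(ds$genomes), function(sp) {
    g <- ds$genomes[[sp]]
    data.frame(species = sp, gene_id = g$gene_id[g$family == "VTR"],
               stringsAsFactors = FALSE)
  }))
  calls <- assign_orthogroups(ds$genomes, cand)
  lam <- calls[calls$species == "lampreys" & calls$gene_id %in%
                 c("VTR1_b", "VTR1_b_t1"), ]
  expect_equal(nrow(lam), 2)
  expect_length(unique(lam$orthogroup), 1)
  # the original (higher shared synteny with the group) is "a", the copy "b"
  expect_equal(lam$suffix[lam$gene_id == "VTR1_b"], "a")
  expect_equal(lam$suffix[lam$gene_id == "VTR1_b_t1"], "b")
})

test_that("locus classification separates loss, territory absence and gaps", {
  consensus <- paste0("T", 1:10)
  # gene absent, territory co-located
  tb1 <- mini_table(paste0("x", 1:12),
                    family = c("Z1", paste0("T", c(1, 3, 5, 7, 9)), paste0("Z", 2:7)))
  expect_equal(classify_locus(tb1, consensus, "FOCUS"), "gene_lost_territory_present")
  # gene and territory absent
  tb2 <- mini_table(paste0("y", 1:12), family = paste0("W", 1:12))
  expect_equal(classify_locus(tb2, consensus, "FOCUS"), "territory_absent")
  # gene present
  tb3 <- mini_table(c("f", paste0("y", 1:5)),
                    family = c("FOCUS", paste0("W", 1:5)))
  expect_equal(classify_locus(tb3, consensus, "FOCUS"), "present")
  # short scaffold carrying partial territory evidence: unresolved
  tb4 <- genome_table(data.frame(
    gene_id = c("s1", "s2", "s3"), chrom = "scaf9", strand = "+",
    family = c("T1", "T2", "Z9")), "sp")
  expect_equal(classify_locus(tb4, consensus, "FOCUS"), "unresolved")
  # statuses partition: exactly one status per call
  for (tb in list(tb1, tb2, tb3, tb4))
    expect_length(classify_locus(tb, consensus, "FOCUS"), 1)
})

test_that("teleost-style VTR1B pattern classifies as the paper describes", {
  ds <- simulate_evolution(h1_receptor_config(), seed = 1)
  cons <- c("P10", "K07", "K06", "K05", "K04",
            "Q06", "K08", "K09", "K10", "K11")
  # teleosts lost the gene but keep the territory
  expect_equal(classify_locus(ds$genomes$teleostei, cons, "VTR1B_FAKE"),
               "gene_lost_territory_present")
})

test_that("end-to-end orthology recovery is exact without rearrangements", {
  # duplications/losses only; focus families recovered exactly vs truth
  base_fams <- paste0("N", 1:20)
  for (seed in 1:5) {
    cfg <- list(tree = "((A,B)ab,(C,D)cd)r;",
                ancestor = list(c1 = c(paste0("N", 1:10), "FOC", paste0("N", 11:20))),
                families = c(FOC = "FOCFAM"),
                rates = c(GENE_LOSS = 2, TANDEM_DUP = 0.5))
    ds <- simulate_evolution(cfg, seed = seed)
    cand <- do.call(rbind, lapply(names(ds$genomes), function(sp) {
      g <- ds$genomes[[sp]]
      if (!any(g$family == "FOCFAM")) return(NULL)
      data.frame(species = sp, gene_id = g$gene_id[g$family == "FOCFAM"],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cand) || length(unique(cand$species)) < 2) next
    calls <- assign_orthogroups(ds$genomes, cand)
    # all focus copies descend from one locus: exactly one orthogroup, and
    # it contains every candidate
    expect_equal(length(unique(calls$orthogroup)), 1, info = paste("seed", seed))
    expect_equal(nrow(calls), nrow(cand), info = paste("seed", seed))
  }
})
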