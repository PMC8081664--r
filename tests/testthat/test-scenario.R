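tree5 <- "((A,B)ab,(C,(D,E)de)cde)r;"

test_that("Dollo places the gain at the MRCA of presence and minimal losses", {
  d <- dollo_reconstruct(tree5, c(A = 1, B = 1, C = 1, D = 1, E = 1))
  expect_equal(d$gain, "r")
  expect_length(d$losses, 0)
  # absences outside the gain clade need no losses at all
  d2 <- dollo_reconstruct(tree5, c(A = 1, B = 1, C = 0, D = 0, E = 0))
  expect_equal(d2$gain, "ab")
  expect_length(d2$losses, 0)
  # absences inside it are covered by one loss per maximal absent subtree
  d2b <- dollo_reconstruct(tree5, c(A = 1, B = 1, C = 1, D = 0, E = 0))
  expect_equal(d2b$gain, "r")
  expect_equal(d2b$losses, "de")
  d3 <- dollo_reconstruct(tree5, c(A = 0, B = 1, C = 1, D = NA, E = 1))
  expect_equal(d3$gain, "r")
  expect_equal(d3$losses, "A")
  expect_error(dollo_reconstruct(tree5, c(A = 0, B = 0, C = 0, D = 0, E = 0)),
               "absent")
})

test_that("Dollo matches the receptor gain/loss statements on the panel tree", {
  m <- presence_matrix_fixture()
  tree <- species_tree_fixture()
  d_vtr2b <- dollo_reconstruct(tree, m["VTR2B", ])
  expect_equal(d_vtr2b$losses, "tetrapoda")     # lost once in the tetrapod stem
  d_vtr1b <- dollo_reconstruct(tree, m["VTR1B", ])
  expect_equal(d_vtr1b$gain, "gnathostomata")   # arose after the lamprey split
  expect_equal(d_vtr1b$losses, "neopterygii")   # lost in holosteans+teleosts
  d_vtr2c <- dollo_reconstruct(tree, m["VTR2C", ])
  expect_equal(d_vtr2c$gain, "osteichthyes")    # after elephant-shark divergence
  expect_equal(d_vtr2c$losses, "birds")
  d_vtr2a <- dollo_reconstruct(tree, m["VTR2A", ])
  expect_setequal(d_vtr2a$losses, c("mammals", "teleostei"))  # independent losses
  d_ot <- dollo_reconstruct(tree, m["OT", ])
  expect_equal(d_ot$gain, "gnathostomata")
  expect_length(d_ot$losses, 0)
})

test_that("Dollo loss counts equal the exhaustive labeling oracle", {
  set.seed(17)
  for (case in 1:40) {
    ntips <- sample(4:8, 1)
    tr <- ape::rtree(ntips, br = NULL)
    tr$tip.label <- paste0("t", seq_len(ntips))
    tr <- read_species_tree(tr)
    pres <- sample(c(1, 0, NA), ntips, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    if (!any(pres %in% 1)) pres[sample(ntips, 1)] <- 1
    names(pres) <- tr$tip.label
    d <- dollo_reconstruct(tr, pres)
    expect_equal(length(d$losses), oracle_dollo_cost(tr, pres),
                 info = paste("case", case))
  }
})

test_that("step counting decomposes compound events and is additive", {
  expect_equal(step_count(list()), 0)
  evs <- list(event("WGD"), event("GENE_LOSS", gene = "x"))
  expect_equal(step_count(evs), 2)
  # translocated segmental duplication = duplication + translocation
  same <- list(event("SEG_DUP", chrom = "c1", from = 0, to = 2, target_chrom = "c1"))
  cross <- list(event("SEG_DUP", chrom = "c1", from = 0, to = 2, target_chrom = "c2"))
  expect_equal(step_count(same), 1)
  expect_equal(step_count(cross), 2)
  h1 <- scenario_h1()
  h2 <- scenario_h2()
  expect_equal(step_count(scenario_concat(h1, h2)),
               step_count(h1) + step_count(h2))
  expect_error(step_count(list(list(kind = "MYSTERY"))), "unknown event kind")
})

test_that("the one-WGD encoding costs 6 steps and the two-WGD encoding 9", {
  expect_equal(step_count(scenario_h1()), 6)
  expect_equal(step_count(scenario_h2()), 9)
})

test_that("scenario replay reproduces observed repertoires and co-locations", {
  h1 <- append_lineage_losses(scenario_h1())
  pred <- apply_scenario(h1)
  # empty scenario leaves every lineage with the ancestor's single receptor
  empty <- scenario(species_tree_fixture(),
                    list(chrM = c("m1", "VTR", "m2")), list(),
                    c(VTR = "VTR"))
  p0 <- apply_scenario(empty)
  expect_true(all(vapply(p0$presence, function(p)
    identical(names(p), "VTR"), logical(1))))
  # birds lack VTR2C, mammals lack VTR2A and VTR2B
  expect_false("VTR2C" %in% names(pred$presence$birds))
  expect_false(any(c("VTR2A", "VTR2B") %in% names(pred$presence$mammals)))
  expect_setequal(names(pred$presence$hagfishes), c("VTR1", "VTR2"))
  obs <- receptor_observation()
  expect_true(scenario_consistent(pred, obs)$consistent)
  h2 <- append_lineage_losses(scenario_h2())
  expect_true(scenario_consistent(apply_scenario(h2), obs)$consistent)
})

test_that("consistency checking itemises presence and co-location violations", {
  h1 <- scenario_h1()   # without the lineage losses
  pred <- apply_scenario(h1)
  obs <- receptor_observation()
  chk <- scenario_consistent(pred, obs)
  expect_false(chk$consistent)
  expect_true(any(grepl("birds: unexpected VTR2C", chk$violations)))
  expect_true(any(grepl("mammals: unexpected VTR2A", chk$violations)))
  # a counter-scenario that strands OTR away from VTR2B
  h1b <- append_lineage_losses(scenario_h1())
  h1b$events <- c(h1b$events,
                  list(event("TRANSLOCATION", branch = "sharks", chrom = "chrM_b",
                             from = 1, to = 2, target_chrom = "chrN_b",
                             target_after = 0)))
  chk2 <- scenario_consistent(apply_scenario(h1b), obs)
  expect_false(chk2$consistent)
  expect_true(any(grepl("sharks: OTR/VTR2B not co-located", chk2$violations)))
})

test_that("minimal-step search solves trivial observations in closed form", {
  tr <- "((A,B)ab,C)r;"
  anc <- c("g1", "g2")
  obs_same <- list(A = anc, B = anc, C = anc)
  res <- min_steps_search(tr, anc, obs_same)
  expect_equal(res$count, 0)
  expect_equal(nrow(res$events), 0)
  obs_loss <- list(A = "g1", B = anc, C = anc)
  res2 <- min_steps_search(tr, anc, obs_loss)
  expect_equal(res2$count, 1)
  expect_equal(res2$events$kind, "loss")
  expect_equal(res2$events$branch, "A")
  # shared loss placed once on the internal branch
  obs_shared <- list(A = "g1", B = "g1", C = anc)
  expect_equal(min_steps_search(tr, anc, obs_shared)$count, 1)
})

test_that("search recovers the cost of known histories (exhaustive oracle)", {
  tr <- "((A,B)ab,C)r;"
  anc <- c("g1", "g2")
  universe <- c("g1", "g2", "g3", "g4")
  set.seed(23)
  for (case in 1:6) {
    nev <- sample(1:4, 1)
    events <- data.frame(branch = character(), kind = character(),
                         class = character(), new_class = character(),
                         stringsAsFactors = FALSE)
    states <- list(r = anc, ab = anc, A = anc, B = anc, C = anc)
    for (i in seq_len(nev)) {
      br <- sample(c("ab", "A", "B", "C"), 1)
      affected <- if (br == "ab") c("ab", "A", "B") else br
      st <- states[[affected[1]]]
      if (!length(st)) next
      if ((length(st) > 1 && runif(1) < 0.5) || !length(setdiff(universe, st))) {
        cl <- sample(st, 1)
        events <- rbind(events, data.frame(branch = br, kind = "loss",
                                           class = cl, new_class = NA))
        for (a in affected) states[[a]] <- setdiff(states[[a]], cl)
      } else {
        new <- sample(setdiff(universe, st), 1)
        events <- rbind(events, data.frame(branch = br, kind = "dup",
                                           class = sample(st, 1), new_class = new))
        for (a in affected) states[[a]] <- union(states[[a]], new)
      }
    }
    observed <- replay_classes(tr, anc, events)
    res <- min_steps_search(tr, anc, observed, universe = universe, max_steps = 6)
    expect_false(is.null(res))
    expect_lte(res$count, nrow(events))
    oracle <- oracle_min_steps(tr, anc, observed, universe, bound = nrow(events))
    expect_equal(res$count, oracle, info = paste("case", case))
    # the found scenario really replays to the observation
    got <- replay_classes(tr, anc, res$events)
    for (l in names(observed))
      expect_equal(sort(got[[l]]), sort(observed[[l]]))
  }
})

test_that("scenario JSON round-trips and replays identically", {
  h1 <- scenario_h1()
  f <- tempfile(fileext = ".json")
  write_scenario_json(h1, f)
  back <- read_scenario_json(f)
  expect_equal(step_count(back), 6)
  p1 <- apply_scenario(h1); p2 <- apply_scenario(back)
  expect_equal(p1$presence, p2$presence)
})
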