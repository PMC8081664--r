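#' Run the packaged synteny workflow end to end
#'
#' Orchestrates the standard stage order - simulate, microsynteny
#' orthology, locus classification, macrosynteny hit counts with the
#' top-two test, paralogon territories, Dollo reconstruction, scenario step
#' counts, gene-tree concordance and universal renaming - on the packaged
#' receptor simulation, writing per-stage TSVs and a JSON summary when
#' `out_dir` is given. The config is validated before any stage runs.
#'
#' @param config list: `stages` (subset of the names above, in order),
#'   `seed`, `out_dir` (optional).
#' @return named list of stage results plus a `summary` list.
#' @export
run_pipeline <- function(config = list()) {
  stages_all <- c("simulate", "microsynteny", "macrosynteny", "paralogon",
                  "scenarios", "concordance", "rename")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ", paste(bad, collapse = ", "))
  need_sim <- c("microsynteny", "macrosynteny", "paralogon")
  if (any(need_sim %in% stages) && !"simulate" %in% stages)
    stop("run_pipeline: stages ", paste(intersect(need_sim, stages), collapse = ", "),
         " need the simulate stage")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  res <- list()
  summary <- list(seed = seed, stages = stages)

  if ("simulate" %in% stages) {
    cfg <- h1_receptor_config()
    res$dataset <- simulate_evolution(cfg, seed = seed)
    res$truth <- truth_orthogroups(res$dataset, cfg$receptor_family)
    emit("truth_status", res$truth)
  }
  if ("microsynteny" %in% stages) {
    ds <- res$dataset
    cand <- do.call(rbind, lapply(names(ds$genomes), function(sp) {
      g <- ds$genomes[[sp]]
      data.frame(species = sp, gene_id = g$gene_id[g$family == "VTR"],
                 stringsAsFactors = FALSE)
    }))
    res$calls <- assign_orthogroups(ds$genomes, cand)
    emit("orthogroups", as.data.frame(res$calls))
    summary$orthogroup_count <- count_orthogroups(res$calls)
    summary$hagfish_receptor_count <-
      sum(ds$genomes$hagfishes$family == "VTR")
  }
  if ("macrosynteny" %in% stages) {
    ds <- res$dataset
    lamprey <- ds$genomes$lampreys
    ref_chrom <- lamprey$chrom[lamprey$gene_id == "VTR1_b"]
    ref <- as.data.frame(lamprey)[lamprey$chrom == ref_chrom, , drop = FALSE]
    counts <- chromosome_hit_counts(ref, ds$genomes$mammals)
    t2 <- top2_test(counts, n_ref_genes = nrow(ref))
    totals <- table(ds$genomes$mammals$chrom)
    dn <- density_normalize(counts[counts > 0],
                            stats::setNames(as.integer(totals), names(totals)))
    res$macro <- list(counts = counts, top2 = t2, density = dn)
    emit("hit_counts", data.frame(chrom = names(counts), hits = as.integer(counts)))
    summary$top2 <- list(chromosomes = t2$top, chi_squared = t2$statistic,
                         p_value = t2$p_value)
    summary$density_flag <- dn$flag
  }
  if ("paralogon" %in% stages) {
    ds <- res$dataset
    coel <- ds$genomes$coelacanth
    anchors <- c(VTR1A = "VTR1_a", OTR = "VTR1_b", VTR2A = "VTR2_a",
                 VTR2B = "VTR2_b", VTR1B = "VTR1B", VTR2C = "VTR2C")
    terr <- lapply(anchors, function(g) territory(coel, g, mode = "genes"))
    ov <- territory_overlap(terr)
    res$paralogon <- ov
    emit("territory_overlap", data.frame(pair = rownames(ov$matrix), ov$matrix,
                                         check.names = FALSE))
    summary$wgd_pair_overlap <- unname(ov$matrix["VTR1A", "OTR"])
    summary$sd_pair_overlap <- unname(ov$matrix["VTR1A", "VTR1B"])
  }
  if ("scenarios" %in% stages) {
    m <- presence_matrix_fixture()
    tree <- species_tree_fixture()
    dollo <- lapply(c("OTR", "VTR1A", "VTR1B", "VTR2A", "VTR2B", "VTR2C"),
                    function(g) dollo_reconstruct(tree, m[g, ]))
    names(dollo) <- c("OTR", "VTR1A", "VTR1B", "VTR2A", "VTR2B", "VTR2C")
    obs <- receptor_observation()
    h1 <- scenario_h1(); h2 <- scenario_h2()
    c1 <- scenario_consistent(apply_scenario(append_lineage_losses(h1)), obs)
    c2 <- scenario_consistent(apply_scenario(append_lineage_losses(h2)), obs)
    res$scenarios <- list(dollo = dollo, h1_consistent = c1, h2_consistent = c2)
    summary$h1_steps <- step_count(h1)
    summary$h2_steps <- step_count(h2)
    summary$dollo <- lapply(dollo, function(d) d[c("gain", "losses")])
    emit("dollo_placements",
         data.frame(gene = names(dollo),
                    gain = vapply(dollo, `[[`, character(1), "gain"),
                    losses = vapply(dollo, function(d)
                      paste(d$losses, collapse = ";"), character(1))))
  }
  if ("concordance" %in% stages) {
    gt <- gene_tree_fixture()
    res$monophyly <- orthogroup_monophyly(gt$tree, gt$map)
    emit("monophyly", res$monophyly)
    summary$monophyly_violators <-
      unlist(strsplit(res$monophyly$violators[!res$monophyly$monophyletic], ";"))
    daln <- make_diagnostic_alignment(seed = seed)
    res$diagnostic <- diagnostic_sites(daln$alignment, daln$group_a, daln$group_b)
    summary$diagnostic_site_count <- nrow(res$diagnostic)
  }
  if ("rename" %in% stages) {
    al <- load_alias_table()
    demo <- rbind(
      data.frame(lineage = "mammals", name = c("AVPR1A", "OXTR", "AVP")),
      data.frame(lineage = "fish", name = c("ITR", "AVPR4")),
      data.frame(lineage = "birds", name = c("VT1", "MT", "VTR2C")))
    rep <- do.call(rbind, lapply(unique(demo$lineage), function(lin) {
      r <- rename_genes(demo$name[demo$lineage == lin], lin, al)
      cbind(lineage = lin, r$report)
    }))
    res$rename <- rep
    emit("rename_report", rep)
  }
  res$summary <- summary
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res
}
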