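#' Ten-gene microsynteny window profile
#'
#' The family labels of the `k` nearest protein-coding genes on each side of
#' a focus gene (nearest first), the core evidence unit of synteny-based
#' orthology assignment. Neighbours without a family label are recorded as
#' anonymous singletons (`anon:<gene_id>`) so they can never match across
#' species.
#'
#' @param table a [genome_table()].
#' @param gene_id focus gene.
#' @param families optional family map ([build_families()] result or named
#'   vector); defaults to the table's own `family` column.
#' @param k window half-width in protein-coding genes (default 5, the
#'   ten-gene window).
#' @param include_noncoding also count miRNA/lncRNA records.
#' @return object of class `window_profile`.
#' @export
window_profile <- function(table, gene_id, families = NULL, k = 5,
                           include_noncoding = FALSE) {
  nb <- neighbors(table, gene_id, k = k, include_noncoding = include_noncoding)
  structure(list(
    focus = gene_id,
    species = species_of(table),
    upstream = gene_families(nb$upstream, families),
    downstream = gene_families(nb$downstream, families),
    strands = c(stats::setNames(nb$upstream$strand, nb$upstream$gene_id),
                stats::setNames(nb$downstream$strand, nb$downstream$gene_id)),
    k = k), class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("window_profile", x$focus, "(", x$species, ") k =", x$k, "\n",
      " 5':", paste(rev(x$upstream), collapse = " "), "\n",
      " 3':", paste(x$downstream, collapse = " "), "\n")
  invisible(x)
}

profile_families <- function(p) {
  unique(c(p$upstream, p$downstream))
}

#' Shared-synteny score between two window profiles
#'
#' Order-free by default: the number of distinct families present in both
#' windows (bounded by 2k). Also reports the longest common ordered sublist
#' of the two full window sequences, for the order-aware variant.
#'
#' @return list(count, matched, lcs).
#' @export
shared_synteny_score <- function(a, b) {
  fa <- profile_families(a)
  fb <- profile_families(b)
  matched <- sort(intersect(fa, fb))
  seq_a <- c(rev(a$upstream), a$downstream)
  seq_b <- c(rev(b$upstream), b$downstream)
  list(count = length(matched), matched = matched, lcs = lcs_length(seq_a, seq_b))
}

lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L else max(d[i, j + 1], d[i + 1, j])
  d[n + 1, m + 1]
}

#' Assign candidate genes to orthogroups by shared microsynteny
#'
#' Greedily groups candidate genes across species: a candidate joins the
#' group whose consensus window it shares at least `min_shared` families
#' with (the best-scoring group on ties of eligibility; ties between groups
#' broken by group creation order). The consensus window of a group is the
#' union of families seen in the windows of at least two member species (a
#' single-member group's consensus is its own window). Candidates are
#' processed from the species with the most annotated windows, so grouping
#' is seeded by the best-annotated genome and is invariant to the input
#' order of species. Within a species, multiple members of one group receive
#' suffixes `a` (highest score), `b`, `c`, ... with ties broken by
#' (chromosome label, order index).
#'
#' @param tables named list species -> [genome_table()].
#' @param candidates data.frame(species, gene_id) of candidate genes (e.g.
#'   every member of a receptor homology family).
#' @param families optional family map used for the windows.
#' @param k window half-width.
#' @param min_shared minimum shared families to join a group (default 3 of
#'   10, the chromosome-scale minimum-aligned-pairs value applied at window
#'   scale).
#' @return data.frame(orthogroup, species, gene_id, suffix, score) of class
#'   `orthology_calls`; attribute `consensus` holds per-group windows.
#' @export
assign_orthogroups <- function(tables, candidates, families = NULL, k = 5,
                               min_shared = 3) {
  stopifnot(min_shared >= 1)
  if (!nrow(candidates)) stop("assign_orthogroups: empty candidate set")
  if (length(tables) < 2) stop("assign_orthogroups: need >= 2 species")
  profs <- vector("list", nrow(candidates))
  annotated <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    p <- window_profile(tables[[candidates$species[i]]], candidates$gene_id[i],
                        families = families, k = k)
    profs[[i]] <- p
    annotated[i] <- sum(!startsWith(profile_families(p), "anon:"))
  }
  sp_rank <- tapply(annotated, candidates$species, sum)
  ord <- order(-sp_rank[candidates$species], candidates$species,
               -annotated, candidates$gene_id)
  groups <- list()   # each: list(members = indices, consensus = families)
  for (i in ord) {
    fams <- profile_families(profs[[i]])
    scores <- vapply(groups, function(g) length(intersect(fams, g$consensus)),
                     integer(1))
    if (length(scores) && max(scores) >= min_shared) {
      j <- which.max(scores)  # first best group on ties
      groups[[j]]$members <- c(groups[[j]]$members, i)
      groups[[j]]$consensus <- group_consensus(profs[groups[[j]]$members], candidates)
    } else {
      groups[[length(groups) + 1]] <- list(members = i, consensus = fams)
    }
  }
  calls <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    idx <- g$members
    score <- vapply(idx, function(i)
      length(intersect(profile_families(profs[[i]]), g$consensus)), integer(1))
    df <- data.frame(orthogroup = candidates$gene_id[idx[1]],
                     species = candidates$species[idx],
                     gene_id = candidates$gene_id[idx],
                     score = score, suffix = NA_character_,
                     stringsAsFactors = FALSE)
    for (sp in unique(df$species)) {
      rows <- which(df$species == sp)
      if (length(rows) > 1) {
        tb <- tables[[sp]]
        pos <- match(df$gene_id[rows], tb$gene_id)
        o <- order(-df$score[rows], tb$chrom[pos], tb$order_index[pos])
        df$suffix[rows[o]] <- letters[seq_along(rows)]
      }
    }
    df
  }))
  rownames(calls) <- NULL
  structure(calls, consensus = lapply(groups, `[[`, "consensus"),
            class = c("orthology_calls", "data.frame"))
}

# union of families seen in windows of >= 2 member species
group_consensus <- function(profs, candidates) {
  if (length(profs) == 1) return(profile_families(profs[[1]]))
  per_sp <- tapply(seq_along(profs),
                   vapply(profs, `[[`, character(1), "species"),
                   function(ix) unique(unlist(lapply(profs[ix], profile_families))))
  tab <- table(unlist(per_sp))
  fams <- names(tab)[tab >= 2]
  if (!length(fams)) unique(unlist(per_sp)) else fams
}

#' @export
print.orthology_calls <- function(x, ...) {
  cat("orthology_calls:", length(unique(x$orthogroup)), "orthogroup(s),",
      nrow(x), "gene(s)\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Number of orthogroups supported by at least `min_species` species
#' @export
count_orthogroups <- function(calls, min_species = 2) {
  n_sp <- tapply(calls$species, calls$orthogroup, function(s) length(unique(s)))
  sum(n_sp >= min_species)
}

#' Classify a locus in one species against a consensus territory
#'
#' Decides, for a species where a focus gene may be missing, whether the
#' gene is truly deleted from an otherwise conserved territory or the whole
#' territory is gone (or unresolvable from a short scaffold). `present` if a
#' candidate gene of the focus family exists; `gene_lost_territory_present`
#' if not, but at least `min_territory` consensus families co-occur within a
#' `span`-gene window; `territory_absent` if fewer; `unresolved` when the
#' only consensus-family evidence sits on a scaffold shorter than `span`
#' genes (an assembly-gap caveat, not an absence call).
#'
#' @param table species [genome_table()].
#' @param consensus character vector of consensus territory families.
#' @param focus_family family label of the focus gene.
#' @param families optional family map.
#' @param min_territory minimum co-occurring consensus families (default 3).
#' @param span window length in genes (default 10).
#' @export
classify_locus <- function(table, consensus, focus_family, families = NULL,
                           min_territory = 3, span = 10) {
  stopifnot(length(consensus) >= 1)
  fam <- gene_families(table, families)
  if (any(fam == focus_family)) return("present")
  best <- 0L
  best_short <- FALSE
  for (ch in unique(table$chrom)) {
    f <- fam[table$chrom == ch][order(table$order_index[table$chrom == ch])]
    n <- length(f)
    for (s in seq_len(max(1, n - span + 1))) {
      w <- f[s:min(n, s + span - 1)]
      cnt <- length(intersect(unique(w), consensus))
      if (cnt > best || (cnt == best && cnt > 0)) {
        if (cnt > best) best_short <- n < span
        else best_short <- best_short && n < span
        best <- max(best, cnt)
      }
    }
  }
  if (best >= min_territory) "gene_lost_territory_present"
  else if (best >= 1 && best_short) "unresolved"
  else "territory_absent"
}
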