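#' Cumulative synteny curve in a 100-gene window
#'
#' Walking outward from a focus gene in the reference genome, the curve
#' increments at each offset whose reference gene has at least one family
#' member in the query species; large conserved stretches appear as steady
#' climbs, breakpoints as plateaus.
#'
#' @param ref_table reference [genome_table()].
#' @param query_table query species table.
#' @param focus focus gene id in the reference.
#' @param families optional family map.
#' @param half_window genes on each side (default 50: a 100-gene window).
#' @return data.frame(offset, hit, cumulative) for offsets -half_window..
#'   +half_window; `cumulative` accumulates outward from 0 per direction.
#' @export
cumulative_profile <- function(ref_table, query_table, focus, families = NULL,
                               half_window = 50) {
  row <- which(ref_table$gene_id == focus)
  if (!length(row)) stop("cumulative_profile: unknown focus '", focus, "'")
  if (!isTRUE(ref_table$placed[row])) stop("cumulative_profile: focus unplaced")
  ch <- ref_table$chrom[row]
  chr <- as.data.frame(ref_table)[ref_table$chrom == ch, , drop = FALSE]
  chr <- chr[order(chr$order_index), , drop = FALSE]
  pos <- which(chr$gene_id == focus)
  fam_ref <- gene_families(chr, families)
  fam_query <- unique(gene_families(query_table, families))
  offs <- (-half_window):half_window
  idx <- pos + offs
  ok <- idx >= 1 & idx <= nrow(chr)
  hit <- ifelse(ok, fam_ref[pmax(idx, 1)] %in% fam_query, NA)
  cum <- integer(length(offs))
  left <- offs < 0; right <- offs > 0
  h0 <- sum(hit[offs == 0], na.rm = TRUE)
  cum[offs == 0] <- h0
  cum[right] <- h0 + cumsum(ifelse(is.na(hit[right]), 0L, hit[right]))
  cum[left] <- h0 + rev(cumsum(ifelse(is.na(rev(hit[left])), 0L, rev(hit[left]))))
  data.frame(offset = offs, hit = hit, cumulative = cum)
}

# homologous gene pairs between two single-chromosome gene lists
homologous_pairs <- function(ref_chr, query_chr, families = NULL) {
  fr <- gene_families(ref_chr, families)
  fq <- gene_families(query_chr, families)
  keep_r <- !startsWith(fr, "anon:")
  keep_q <- !startsWith(fq, "anon:")
  m <- merge(data.frame(ref_index = ref_chr$order_index[keep_r],
                        ref_gene = ref_chr$gene_id[keep_r], fam = fr[keep_r]),
             data.frame(query_index = query_chr$order_index[keep_q],
                        query_gene = query_chr$gene_id[keep_q], fam = fq[keep_q]),
             by = "fam")
  m[order(m$ref_index, m$query_index), c("ref_index", "query_index",
                                         "ref_gene", "query_gene")]
}

#' Collinear chains between two chromosomes
#'
#' Finds all maximal runs of homologous gene pairs whose positions are
#' strictly monotone on both genomes (increasing: co-linear; decreasing in
#' the query: anti-diagonal, i.e. inverted), with consecutive pairs at most
#' `max_gap` genes apart on both axes, and at least `min_pairs` pairs long -
#' the gene-level equivalent of a syntenic dot-plot block. A chain is
#' maximal when no pair can be prepended or appended under the same rules.
#'
#' @param ref_chr,query_chr single-chromosome [genome_table()] subsets (or
#'   data.frames with gene_id/order_index/family).
#' @param families optional family map.
#' @param min_pairs minimum pairs per chain (3 for close comparisons, 2 for
#'   distant ones).
#' @param max_gap maximum index gap between consecutive pairs (default 20).
#' @return list of chains: list(pairs = data.frame(ref_index, query_index,
#'   ref_gene, query_gene), orientation = "colinear"|"anti").
#' @export
collinear_chains <- function(ref_chr, query_chr, families = NULL,
                             min_pairs = 3, max_gap = 20) {
  stopifnot(min_pairs >= 1, max_gap >= 1)
  pairs <- homologous_pairs(ref_chr, query_chr, families)
  chains_from_pairs(pairs, min_pairs, max_gap)
}

chains_from_pairs <- function(pairs, min_pairs, max_gap) {
  n <- nrow(pairs)
  if (!n) return(list())
  out <- list()
  for (sign in c(1L, -1L)) {
    # edge i -> j: j can follow i in a chain of this orientation
    succ <- lapply(seq_len(n), function(i) {
      d_ref <- pairs$ref_index - pairs$ref_index[i]
      d_q <- sign * (pairs$query_index - pairs$query_index[i])
      which(d_ref > 0 & d_ref <= max_gap & d_q > 0 & d_q <= max_gap)
    })
    has_pred <- rep(FALSE, n)
    for (i in seq_len(n)) has_pred[succ[[i]]] <- TRUE
    # a maximal chain can only step to *immediate* successors: if some pair
    # m fits strictly between i and j, the chain skipping m is not maximal
    # (any insertable pair shrinks both gaps, so it is always linkable)
    succ_imm <- lapply(seq_len(n), function(i) {
      s <- succ[[i]]
      s[!vapply(s, function(j) any(vapply(s, function(m) j %in% succ[[m]],
                                          logical(1))), logical(1))]
    })
    # DFS over immediate-successor paths from pairs with no predecessor:
    # such paths are exactly the maximal chains
    walk <- function(path) {
      nxt <- succ_imm[[path[length(path)]]]
      if (!length(nxt)) {
        if (length(path) >= min_pairs)
          out[[length(out) + 1]] <<- list(
            pairs = pairs[path, , drop = FALSE],
            orientation = if (sign == 1L) "colinear" else "anti")
        return(invisible())
      }
      for (j in nxt) walk(c(path, j))
    }
    for (i in which(!has_pred)) walk(i)
  }
  # deterministic order: longer first, then smaller starting ref index
  if (length(out)) {
    key <- vapply(out, function(ch) c(-nrow(ch$pairs), ch$pairs$ref_index[1],
                                      ch$pairs$query_index[1]), numeric(3))
    out <- out[order(key[1, ], key[2, ], key[3, ])]
  }
  out
}

#' Syntenic gene hits per query chromosome
#'
#' For one reference chromosome, counts per query chromosome the number of
#' distinct reference genes that participate in at least one collinear
#' chain to that chromosome (the bar heights of a dot-plot summary).
#'
#' @inheritParams collinear_chains
#' @param ref_chr single-chromosome reference subset.
#' @param query_table full query [genome_table()].
#' @return named integer vector, sorted by decreasing count then label.
#' @export
chromosome_hit_counts <- function(ref_chr, query_table, families = NULL,
                                  min_pairs = 3, max_gap = 20) {
  counts <- integer(0)
  for (qc in unique(query_table$chrom)) {
    qchr <- as.data.frame(query_table)[query_table$chrom == qc, , drop = FALSE]
    ch <- collinear_chains(ref_chr, qchr, families, min_pairs, max_gap)
    genes <- unique(unlist(lapply(ch, function(x) x$pairs$ref_gene)))
    counts[qc] <- length(genes)
  }
  counts <- counts[order(-counts, names(counts))]
  counts
}

#' Chi-squared comparison of the two best-hit chromosomes
#'
#' Tests the difference in syntenic-hit proportions between the two query
#' chromosomes with the highest gene-hit counts, using the reference
#' scaffold's gene count as the sample size for both: a 2x2 table
#' [hits1, n - hits1; hits2, n - hits2], chi-squared = sum((O-E)^2/E),
#' df = 1, two-sided, no continuity correction, plus a Wald confidence
#' interval for the proportion difference.
#'
#' @param counts named hit counts per query chromosome (>= 2 nonzero).
#' @param n_ref_genes number of genes on the reference scaffold.
#' @param conf confidence level for the Wald interval.
#' @return list(top, counts_top, table, statistic, df, p_value, ci).
#' @export
top2_test <- function(counts, n_ref_genes, conf = 0.95) {
  counts <- counts[order(-counts, names(counts))]
  if (sum(counts > 0) < 2) stop("top2_test: need >= 2 chromosomes with hits")
  h <- counts[1:2]
  if (any(h > n_ref_genes)) stop("top2_test: count exceeds reference gene total")
  tab <- rbind(c(h[1], n_ref_genes - h[1]), c(h[2], n_ref_genes - h[2]))
  dimnames(tab) <- list(names(h), c("hit", "no_hit"))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p1 <- h[1] / n_ref_genes; p2 <- h[2] / n_ref_genes
  se <- sqrt(p1 * (1 - p1) / n_ref_genes + p2 * (1 - p2) / n_ref_genes)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(top = names(h), counts_top = unname(h), table = tab,
       statistic = unname(stat), df = 1L, p_value = unname(p),
       ci = unname(c((p1 - p2) - z * se, (p1 - p2) + z * se)))
}

#' Gene-density normalization of chromosome hit counts
#'
#' Rules out the possibility that the top-hit chromosome simply carries the
#' most genes: reports hits per gene for each query chromosome, the
#' Spearman rank correlation between raw counts and chromosome gene totals,
#' and a flag raised when the top chromosome by rate differs from the top
#' by raw count.
#'
#' @param counts named hit counts.
#' @param totals named gene totals per query chromosome (positive).
#' @export
density_normalize <- function(counts, totals) {
  totals <- totals[names(counts)]
  if (any(is.na(totals) | totals <= 0))
    stop("density_normalize: missing or non-positive chromosome gene total")
  rate <- counts / totals
  ct <- suppressWarnings(stats::cor.test(as.numeric(counts), as.numeric(totals),
                                         method = "spearman", exact = FALSE))
  top_count <- names(counts)[order(-counts, names(counts))][1]
  top_rate <- names(rate)[order(-rate, names(rate))][1]
  list(rate = rate, rho = unname(ct$estimate), p_value = ct$p.value,
       top_by_count = top_count, top_by_rate = top_rate,
       flag = top_count != top_rate)
}
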