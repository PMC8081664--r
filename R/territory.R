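#' Syntenic territory around an anchor
#'
#' All genes within a window of an anchor gene (or of the matched span of
#' an anchor gene *set*, for deleted loci): 10-Mb in base pairs when
#' coordinates exist, otherwise the 40 nearest genes - the two window
#' specs the 10-Mb intraspecies macrosynteny scale treats as equivalent.
#'
#' @param table [genome_table()].
#' @param anchor gene id, or character vector of anchor gene ids on one
#'   chromosome (e.g. from [deleted_locus_anchor()]).
#' @param window_bp bp window width (total; half each side of the anchor
#'   midpoint). Default 1e7.
#' @param window_genes gene-count fallback window (total). Default 40.
#' @param mode "auto" (bp when coordinates exist), "bp" or "genes".
#' @return object of class `territory`: list(species, anchor, chrom, mode,
#'   members, families).
#' @export
territory <- function(table, anchor, window_bp = 1e7, window_genes = 40,
                      mode = c("auto", "bp", "genes")) {
  mode <- match.arg(mode)
  rows <- match(anchor, table$gene_id)
  if (anyNA(rows)) stop("territory: unknown anchor gene(s): ",
                        paste(anchor[is.na(rows)], collapse = ", "))
  if (length(unique(table$chrom[rows])) != 1)
    stop("territory: anchor genes span several chromosomes; pick one side")
  if (!all(table$placed[rows] %in% TRUE))
    stop("territory: anchor unplaced")
  ch <- table$chrom[rows[1]]
  chr <- as.data.frame(table)[table$chrom == ch, , drop = FALSE]
  chr <- chr[order(chr$order_index), , drop = FALSE]
  have_bp <- !anyNA(chr$start) && !anyNA(chr$end)
  if (mode == "auto") mode <- if (have_bp) "bp" else "genes"
  if (mode == "bp") {
    if (!have_bp) stop("territory: bp mode needs coordinates")
    mid <- mean((table$start[rows] + table$end[rows]) / 2)
    gene_mid <- (chr$start + chr$end) / 2
    members <- chr[abs(gene_mid - mid) <= window_bp / 2, , drop = FALSE]
  } else {
    center <- mean(match(anchor, chr$gene_id))
    o <- order(abs(seq_len(nrow(chr)) - center))
    members <- chr[sort(o[seq_len(min(window_genes + length(anchor), nrow(chr)))]), ,
                   drop = FALSE]
  }
  structure(list(species = species_of(table), anchor = anchor, chrom = ch,
                 mode = mode, members = members,
                 families = setdiff(unique(gene_families(members)),
                                    paste0("anon:", anchor))),
            class = "territory")
}

#' @export
print.territory <- function(x, ...) {
  cat("territory of", paste(x$anchor, collapse = "+"), "(", x$species, ",",
      x$chrom, ",", x$mode, "mode ):", nrow(x$members), "genes,",
      length(x$families), "families\n")
  invisible(x)
}

#' Anchor a deleted locus via a donor species that retains the gene
#'
#' Takes the ten-gene flanking families of the focus gene in a donor genome
#' that still has it, finds those families in a target genome where the
#' gene is deleted, and returns the matched target genes to serve as the
#' anchor set for [territory()]. When the matched flank families land on
#' two chromosomes (upstream block on one, downstream block on another) the
#' split is reported - the fission signature seen at the mammalian VTR2A
#' locus.
#'
#' @param donor_table genome retaining the gene.
#' @param target_table genome where the gene is deleted.
#' @param gene_id focus gene id in the donor.
#' @param families optional family map shared by both tables.
#' @param k flank half-width in the donor (default 5).
#' @return list(anchors = data.frame(gene_id, chrom, side), split,
#'   chromosomes).
#' @export
deleted_locus_anchor <- function(donor_table, target_table, gene_id,
                                 families = NULL, k = 5) {
  nb <- neighbors(donor_table, gene_id, k = k)
  up_f <- gene_families(nb$upstream, families)
  down_f <- gene_families(nb$downstream, families)
  tf <- gene_families(target_table, families)
  hit_up <- which(tf %in% up_f)
  hit_down <- which(tf %in% down_f)
  found <- data.frame(
    gene_id = c(target_table$gene_id[hit_up], target_table$gene_id[hit_down]),
    chrom = c(target_table$chrom[hit_up], target_table$chrom[hit_down]),
    side = rep(c("5'", "3'"), c(length(hit_up), length(hit_down))),
    stringsAsFactors = FALSE)
  n_fam <- length(intersect(tf, c(up_f, down_f)))
  if (n_fam < 2)
    stop("deleted_locus_anchor: territory untraceable (<2 flanking families in target)")
  chroms <- unique(found$chrom)
  split <- length(chroms) > 1
  list(anchors = found, split = split, chromosomes = chroms)
}

#' Pairwise shared-family counts between territories
#'
#' Symmetric matrix of the number of distinct gene families present in both
#' territories; the diagonal is each territory's own family count. Shared
#' family lists are attached. Family identity, not gene identity, defines
#' overlap, so paralogons (e.g. the two products of a whole-genome
#' duplication) show up as high off-diagonal counts.
#'
#' @param territories list of [territory()] objects (>= 2), optionally
#'   named.
#' @return list(matrix, shared).
#' @export
territory_overlap <- function(territories) {
  stopifnot(length(territories) >= 2)
  nm <- names(territories)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(territories, function(t) paste(t$anchor, collapse = "+"),
                 character(1))
  k <- length(territories)
  m <- matrix(0L, k, k, dimnames = list(nm, nm))
  shared <- list()
  fams <- lapply(territories, function(t) setdiff(t$families,
                                                  grep("^anon:", t$families, value = TRUE)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    common <- if (i == j) fams[[i]] else intersect(fams[[i]], fams[[j]])
    m[i, j] <- length(common)
    if (i < j) shared[[paste(nm[i], nm[j], sep = "|")]] <- sort(common)
  }
  list(matrix = m, shared = shared)
}
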