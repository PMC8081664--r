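#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the denominator
#' (masked bases carry no GC information). A sequence with no effective
#' length returns `NA` with a warning rather than a number.
#'
#' @param sequence single string over A, C, G, T, N (case-insensitive).
#' @export
gc_content <- function(sequence) {
  stopifnot(length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("gc_content: non-nucleotide character(s): ",
                        paste(bad, collapse = ", "))
  eff <- sum(chars %in% c("A", "C", "G", "T"))
  if (!eff) {
    warning("gc_content: no unmasked bases; undefined")
    return(NA_real_)
  }
  100 * sum(chars %in% c("G", "C")) / eff
}

#' Exon/intron structure of a gene
#'
#' @param gene_id id.
#' @param exons data.frame or matrix with columns start, end (bp, 0-based
#'   half-open), non-overlapping.
#' @param sequence optional genomic sequence of the locus (0-based offsets
#'   matching the exon coordinates) for per-intron GC.
#' @export
gene_structure <- function(gene_id, exons, sequence = NULL) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start)) stop("gene_structure: exon end <= start")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("gene_structure: overlapping exons")
  introns <- if (nrow(exons) > 1)
    data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1])
  else data.frame(start = numeric(), end = numeric())
  structure(list(gene_id = gene_id, exons = exons, introns = introns,
                 sequence = sequence), class = "gene_structure")
}

#' Rank-aligned intron length comparison of two genes
#'
#' Compares introns by rank (first vs first, ...), reporting lengths, the
#' length ratio a/b and which gene is shorter at each rank - the signature
#' used to ask whether a duplicate gene (e.g. OT) shows intron shortening
#' relative to its parent (VT). Mismatched intron counts are compared up to
#' the shorter list and flagged.
#'
#' @param a,b [gene_structure()] objects with >= 1 intron each.
#' @return data.frame(rank, len_a, len_b, ratio, shorter, gc_a, gc_b) with
#'   attribute `count_mismatch`.
#' @export
intron_metrics <- function(a, b) {
  na <- nrow(a$introns); nb <- nrow(b$introns)
  if (!na || !nb) stop("intron_metrics: both genes need >= 1 intron")
  n <- min(na, nb)
  intron_gc <- function(g, i) {
    if (is.null(g$sequence)) return(NA_real_)
    gc_content(substr(g$sequence, g$introns$start[i] + 1, g$introns$end[i]))
  }
  out <- data.frame(rank = seq_len(n),
                    len_a = (a$introns$end - a$introns$start)[seq_len(n)],
                    len_b = (b$introns$end - b$introns$start)[seq_len(n)])
  out$ratio <- out$len_a / out$len_b
  out$shorter <- ifelse(out$len_a < out$len_b, a$gene_id,
                        ifelse(out$len_b < out$len_a, b$gene_id, "tie"))
  out$gc_a <- vapply(seq_len(n), function(i) intron_gc(a, i), numeric(1))
  out$gc_b <- vapply(seq_len(n), function(i) intron_gc(b, i), numeric(1))
  attr(out, "count_mismatch") <- na != nb
  out
}

#' Scan for TE-TIR repeats flanking a gene
#'
#' Returns the terminal-inverted-repeat transposable elements overlapping
#' `[start - window_bp, end + window_bp)` of the gene, with the flank side
#' (5'/3' in genomic orientation) and distance to the gene boundary.
#' Cut-and-paste TE-TIRs found around a gene but not its paralogue are the
#' mechanistic fingerprint of a TE-mediated tandem duplication.
#'
#' @param table [genome_table()] with coordinates.
#' @param gene_id focus gene.
#' @param repeats data.frame(chrom, start, end, repeat_class, has_tir).
#' @param window_bp flank width in bp.
#' @export
te_flank_scan <- function(table, gene_id, repeats, window_bp = 10000) {
  row <- which(table$gene_id == gene_id)
  if (!length(row)) stop("te_flank_scan: unknown gene '", gene_id, "'")
  gs <- table$start[row]; ge <- table$end[row]
  if (is.na(gs) || is.na(ge)) stop("te_flank_scan: gene has no coordinates")
  r <- repeats[repeats$has_tir & repeats$chrom == table$chrom[row] &
               repeats$end > gs - window_bp & repeats$start < ge + window_bp, ,
               drop = FALSE]
  if (!nrow(r)) return(cbind(r, side = character(0), distance = numeric(0)))
  r$side <- ifelse(r$end <= gs, "5'", ifelse(r$start >= ge, "3'", "overlap"))
  r$distance <- ifelse(r$end <= gs, gs - r$end, ifelse(r$start >= ge, r$start - ge, 0))
  rownames(r) <- NULL
  r
}

#' Relative transcriptional orientation of two adjacent genes
#'
#' Classifies the pair in chromosomal order as `tail_to_head` (same strand:
#' one gene's 3' end points at the next gene's 5' end), `tail_to_tail`
#' (strands converge: 3' ends face each other) or `head_to_head` (strands
#' diverge). When the pair is not tail-to-head, the inverted member is the
#' gene whose strand disagrees with the majority strand of its `k`-gene
#' neighbourhood (the pair itself excluded); a majority tie yields `none`
#' with a flag.
#'
#' @param table [genome_table()] with strands.
#' @param gene_a,gene_b gene ids on one chromosome.
#' @param k neighbourhood half-width for majority-strand attribution.
#' @return list(class, first, second, inverted, tie).
#' @export
pair_orientation <- function(table, gene_a, gene_b, k = 5) {
  ra <- which(table$gene_id == gene_a); rb <- which(table$gene_id == gene_b)
  if (!length(ra) || !length(rb)) stop("pair_orientation: unknown gene")
  if (table$chrom[ra] != table$chrom[rb])
    stop("pair_orientation: genes on different chromosomes")
  if (is.na(table$strand[ra]) || is.na(table$strand[rb]))
    stop("pair_orientation: missing strand")
  if (table$order_index[ra] > table$order_index[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
  s1 <- table$strand[ra]; s2 <- table$strand[rb]
  cls <- if (s1 == s2) "tail_to_head"
         else if (s1 == "+") "tail_to_tail"   # 3' ends converge
         else "head_to_head"                  # 5' ends diverge
  inverted <- "none"; tie <- FALSE
  if (cls != "tail_to_head") {
    majority <- function(row) {
      nb <- neighbors(table, table$gene_id[row], k = k)
      s <- c(nb$upstream$strand, nb$downstream$strand)
      s <- s[!is.na(s) & !(c(nb$upstream$gene_id, nb$downstream$gene_id) %in%
                             table$gene_id[c(ra, rb)])]
      diff <- sum(s == "+") - sum(s == "-")
      if (diff > 0) "+" else if (diff < 0) "-" else NA_character_
    }
    ma <- majority(ra); mb <- majority(rb)
    disagree <- c(!is.na(ma) && ma != s1, !is.na(mb) && mb != s2)
    if (sum(disagree) == 1) {
      inverted <- table$gene_id[c(ra, rb)][disagree]
    } else {
      tie <- TRUE
    }
  }
  list(class = cls, first = table$gene_id[ra], second = table$gene_id[rb],
       inverted = inverted, tie = tie)
}
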