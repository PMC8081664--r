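#' Elementary genome-evolution events
#'
#' Constructs one replayable event. Segment ranges are 0-based half-open
#' `[from, to)` over `order_index` on a chromosome. Supported kinds:
#'
#' * `TANDEM_DUP(gene, copy_id, mark_te_flank)` - inserts a copy directly
#'   downstream of the source, same strand (tail-to-head). With
#'   `mark_te_flank = TRUE` a TE-TIR marker is recorded flanking the copy,
#'   emulating the cut-and-paste transposition footprint expected at the
#'   donor site of a transposable-element-mediated duplication.
#' * `SEG_DUP(chrom, from, to, target_chrom, target_after, copy_ids)` -
#'   copies a contiguous segment to a stated location (`target_after` is the
#'   order index after which the copy is inserted; -1 inserts at the start;
#'   default appends at the chromosome end). A segmental duplication whose
#'   target lies on a different chromosome is a *translocated* segmental
#'   duplication.
#' * `TRANSLOCATION(chrom, from, to, target_chrom, target_after)` - moves a
#'   segment.
#' * `WGD()` - duplicates every chromosome; copies of chromosome `cN` are
#'   named `cN_a` / `cN_b` and gene ids suffixed `_a` / `_b`.
#' * `GENE_LOSS(gene)`, `SEGMENT_LOSS(chrom, from, to)`.
#' * `INVERSION(chrom, from, to)` - reverses order and flips strands.
#' * `FISSION(chrom, at)` - splits before index `at` into `chrom_p1` /
#'   `chrom_p2`.
#'
#' @param kind event kind (see above).
#' @param branch species-tree branch the event occurs on (label of the node
#'   below the branch); `NA` for events applied to the root ancestor.
#' @param ... payload fields.
#' @export
event <- function(kind, branch = NA_character_, ...) {
  kinds <- c("TANDEM_DUP", "SEG_DUP", "TRANSLOCATION", "WGD", "GENE_LOSS",
             "SEGMENT_LOSS", "INVERSION", "FISSION")
  if (!kind %in% kinds) stop("unknown event kind '", kind, "'")
  structure(c(list(kind = kind, branch = branch), list(...)), class = "evo_event")
}

#' @export
print.evo_event <- function(x, ...) {
  pay <- x[setdiff(names(x), c("kind", "branch"))]
  cat(sprintf("<%s on %s: %s>\n", x$kind,
              ifelse(is.na(x$branch), "root", x$branch),
              paste(names(pay), vapply(pay, function(v) paste(v, collapse = ","),
                                       character(1)), sep = "=", collapse = " ")))
  invisible(x)
}

ev_describe <- function(ev) {
  sprintf("%s on branch %s", ev$kind, ifelse(is.na(ev$branch), "root", ev$branch))
}

chrom_rows <- function(genes, chrom) {
  rows <- which(genes$chrom == chrom)
  rows[order(genes$order_index[rows])]
}

check_range <- function(genes, ev) {
  rows <- chrom_rows(genes, ev$chrom)
  if (!length(rows)) stop("event payload out of range (", ev_describe(ev),
                          "): no chromosome '", ev$chrom, "'")
  n <- length(rows)
  if (is.null(ev$from) || is.null(ev$to) || ev$from < 0 || ev$to > n || ev$from >= ev$to)
    stop("event payload out of range (", ev_describe(ev), "): segment [",
         ev$from, ",", ev$to, ") on ", n, " genes")
  rows
}

fresh_suffix <- function(ids, base, pre) {
  i <- 1L
  repeat {
    cand <- paste0(base, pre, i)
    if (!cand %in% ids) return(list(id = cand, i = i))
    i <- i + 1L
  }
}

#' Apply one event to a genome
#'
#' Deterministic replay semantics: applying the same event to the same
#' genome always yields the same genome. `order_index` is reindexed to
#' restore the 0..n-1 invariant; base-pair coordinates of modified
#' chromosomes are invalidated (reassign with [assign_coordinates()]).
#'
#' @param genome a [genome_table()].
#' @param ev an [event()].
#' @export
apply_event <- function(genome, ev) {
  stopifnot(inherits(ev, "evo_event"))
  genes <- as.data.frame(genome)
  sp <- species_of(genome)
  marks <- attr(genome, "te_marks")
  if (is.null(marks)) marks <- data.frame(chrom = character(), gene_id = character(),
                                          stringsAsFactors = FALSE)
  touched <- character(0)

  if (ev$kind == "TANDEM_DUP") {
    row <- which(genes$gene_id == ev$gene)
    if (!length(row)) stop("event payload out of range (", ev_describe(ev),
                           "): no gene '", ev$gene, "'")
    copy <- genes[row, , drop = FALSE]
    fs <- fresh_suffix(genes$gene_id, ev$gene, "_t")
    copy$gene_id <- if (!is.null(ev$copy_id)) ev$copy_id else fs$id
    if (copy$gene_id %in% genes$gene_id)
      stop("TANDEM_DUP copy id '", copy$gene_id, "' already exists")
    copy$locus <- paste0(genes$locus[row], "/t", fs$i)
    copy$order_index <- genes$order_index[row] + 0.5  # sorts just after source
    genes <- rbind(genes, copy)
    touched <- ev$chrom <- genes$chrom[row]
    if (isTRUE(ev$mark_te_flank))
      marks <- rbind(marks, data.frame(chrom = copy$chrom, gene_id = copy$gene_id,
                                       stringsAsFactors = FALSE))
  } else if (ev$kind == "SEG_DUP" || ev$kind == "TRANSLOCATION") {
    rows <- check_range(genes, ev)
    seg_rows <- rows[(ev$from + 1):ev$to]
    target <- if (!is.null(ev$target_chrom)) ev$target_chrom else ev$chrom
    moving <- ev$kind == "TRANSLOCATION"
    seg <- genes[seg_rows, , drop = FALSE]
    if (!moving) {
      if (!is.null(ev$copy_ids)) {
        if (length(ev$copy_ids) != nrow(seg))
          stop("SEG_DUP: copy_ids length != segment size (", ev_describe(ev), ")")
        if (any(ev$copy_ids %in% genes$gene_id))
          stop("SEG_DUP: copy id already exists (", ev_describe(ev), ")")
        seg$gene_id <- ev$copy_ids
        seg$locus <- paste0(seg$locus, "/s1")
      } else {
        for (j in seq_len(nrow(seg))) {
          fs <- fresh_suffix(genes$gene_id, seg$gene_id[j], "_s")
          seg$locus[j] <- paste0(seg$locus[j], "/s", fs$i)
          seg$gene_id[j] <- fs$id
        }
      }
    }
    trows <- chrom_rows(genes, target)
    if (!length(trows) && target != ev$chrom)
      stop("event payload out of range (", ev_describe(ev), "): no target chromosome '",
           target, "'")
    after <- if (!is.null(ev$target_after)) ev$target_after else length(trows) - 1L
    if (after < -1 || after > length(trows) - 1L)
      stop("event payload out of range (", ev_describe(ev), "): target_after ", after)
    seg$chrom <- target
    seg$order_index <- after + seq_len(nrow(seg)) / (nrow(seg) + 1)
    if (moving) genes <- genes[-seg_rows, , drop = FALSE]
    genes <- rbind(genes, seg)
    touched <- c(ev$chrom, target)
  } else if (ev$kind == "WGD") {
    a <- genes; b <- genes
    a$chrom <- paste0(a$chrom, "_a"); b$chrom <- paste0(b$chrom, "_b")
    a$gene_id <- paste0(a$gene_id, "_a"); b$gene_id <- paste0(b$gene_id, "_b")
    a$locus <- paste0(a$locus, "/a"); b$locus <- paste0(b$locus, "/b")
    genes <- rbind(a, b)
    if (nrow(marks)) {
      marks <- rbind(data.frame(chrom = paste0(marks$chrom, "_a"),
                                gene_id = paste0(marks$gene_id, "_a")),
                     data.frame(chrom = paste0(marks$chrom, "_b"),
                                gene_id = paste0(marks$gene_id, "_b")))
    }
    touched <- unique(genes$chrom)
  } else if (ev$kind == "GENE_LOSS") {
    row <- which(genes$gene_id == ev$gene)
    if (!length(row)) stop("event payload out of range (", ev_describe(ev),
                           "): no gene '", ev$gene, "'")
    touched <- genes$chrom[row]
    genes <- genes[-row, , drop = FALSE]
  } else if (ev$kind == "SEGMENT_LOSS") {
    rows <- check_range(genes, ev)
    genes <- genes[-rows[(ev$from + 1):ev$to], , drop = FALSE]
    touched <- ev$chrom
  } else if (ev$kind == "INVERSION") {
    rows <- check_range(genes, ev)
    seg <- rows[(ev$from + 1):ev$to]
    genes$order_index[seg] <- rev(genes$order_index[seg])
    genes$strand[seg] <- c("+" = "-", "-" = "+")[genes$strand[seg]]
    touched <- ev$chrom
  } else if (ev$kind == "FISSION") {
    rows <- chrom_rows(genes, ev$chrom)
    if (!length(rows)) stop("event payload out of range (", ev_describe(ev),
                            "): no chromosome '", ev$chrom, "'")
    if (is.null(ev$at) || ev$at <= 0 || ev$at >= length(rows))
      stop("event payload out of range (", ev_describe(ev), "): split at ", ev$at)
    p1 <- rows[seq_len(ev$at)]
    sel <- marks$chrom == ev$chrom
    marks$chrom[sel] <- ifelse(marks$gene_id[sel] %in% genes$gene_id[p1],
                               paste0(ev$chrom, "_p1"), paste0(ev$chrom, "_p2"))
    genes$chrom[p1] <- paste0(ev$chrom, "_p1")
    genes$chrom[setdiff(rows, p1)] <- paste0(ev$chrom, "_p2")
    touched <- c(paste0(ev$chrom, "_p1"), paste0(ev$chrom, "_p2"))
  }

  marks <- marks[marks$gene_id %in% genes$gene_id, , drop = FALSE]
  genes$start[genes$chrom %in% touched] <- NA_real_
  genes$end[genes$chrom %in% touched] <- NA_real_
  out <- rebuild_table(genes, sp)
  attr(out, "te_marks") <- marks
  out
}

#' Replay an ordered event list
#' @export
apply_events <- function(genome, events) {
  for (ev in events) genome <- apply_event(genome, ev)
  genome
}

#' Assign synthetic base-pair coordinates along each chromosome
#'
#' Lays genes out uniformly (`start = order_index * spacing`), filling
#' missing strands with "+". Used after simulation so that base-pair window
#' operations and TE-flank scans can run on synthetic genomes.
#' @export
assign_coordinates <- function(table, spacing = 10000, width = 5000) {
  genes <- as.data.frame(table)
  genes$start <- genes$order_index * spacing
  genes$end <- genes$start + width
  genes$strand[is.na(genes$strand)] <- "+"
  out <- rebuild_table(genes, species_of(table))
  attr(out, "te_marks") <- attr(table, "te_marks")
  out
}

#' TE-TIR repeat track implied by tandem-duplication marks
#'
#' Emits one terminal-inverted-repeat DNA-transposon interval in the
#' intergenic space 5' of each marked duplicate copy (coordinates must have
#' been assigned). BED-like: chrom, start, end, class, has_tir.
#' @export
te_repeat_track <- function(table, tir_width = 300, offset = 500) {
  marks <- attr(table, "te_marks")
  if (is.null(marks) || !nrow(marks))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      repeat_class = character(), has_tir = logical()))
  rows <- match(marks$gene_id, table$gene_id)
  if (anyNA(table$start[rows]))
    stop("te_repeat_track: assign_coordinates() first")
  data.frame(chrom = table$chrom[rows],
             start = pmax(0, table$start[rows] - offset - tir_width),
             end = pmax(tir_width, table$start[rows] - offset),
             repeat_class = "DNA/TIR", has_tir = TRUE,
             stringsAsFactors = FALSE)
}
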