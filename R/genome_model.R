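#' Gene-order table for one species
#'
#' The central container of the package: one row per gene, ordered along each
#' chromosome by `order_index` (0-based rank). Gene order, not base-pair
#' position, is the primary axis of every synteny operation; coordinates are
#' optional (0-based half-open) and used only by base-pair window operations
#' such as [territory()] and [te_flank_scan()].
#'
#' @param genes data.frame with at least `gene_id` and `chrom`. Optional
#'   columns: `start`, `end` (0-based half-open), `strand` ("+"/"-"),
#'   `family`, `biotype` (`protein_coding`, `miRNA`, `lncRNA`, `other`),
#'   `placed` (logical; unplaced scaffolds are retained, never dropped),
#'   `aliases` (";"-separated), `order_index`, `locus` (lineage identifier
#'   used by the simulator's ground truth).
#' @param species species name attached to the table.
#' @return object of class `genome_table` (a data.frame).
#' @export
genome_table <- function(genes, species) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom")
  miss <- setdiff(required, names(genes))
  if (length(miss)) stop("genome_table: missing columns: ", paste(miss, collapse = ", "))
  defaults <- list(start = NA_real_, end = NA_real_, strand = NA_character_,
                   family = NA_character_, biotype = "protein_coding",
                   placed = TRUE, aliases = NA_character_)
  for (nm in names(defaults)) if (is.null(genes[[nm]]))
    genes[[nm]] <- rep(defaults[[nm]], nrow(genes))
  if (is.null(genes$locus)) genes$locus <- genes$gene_id
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$gene_id))
    stop("genome_table: duplicate gene_id within species '", species, "': ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  ok_coord <- !is.na(genes$start) & !is.na(genes$end)
  if (any(ok_coord & genes$end <= genes$start))
    stop("genome_table: end must be > start (0-based half-open)")
  if (is.null(genes$order_index)) {
    genes <- genes[order(genes$chrom,
                         ifelse(is.na(genes$start), 0, genes$start),
                         ifelse(is.na(genes$end), 0, genes$end),
                         genes$gene_id), , drop = FALSE]
    genes <- reindex_orders(genes)
  } else {
    genes <- genes[order(genes$chrom, genes$order_index), , drop = FALSE]
    bad <- vapply(split(genes$order_index, genes$chrom),
                  function(ix) !identical(as.integer(sort(ix)), seq_along(ix) - 1L),
                  logical(1))
    if (any(bad)) stop("genome_table: order_index must be 0..n-1 per chromosome (",
                       paste(names(bad)[bad], collapse = ", "), ")")
  }
  canon <- c("gene_id", "chrom", "order_index", "start", "end", "strand",
             "family", "biotype", "placed", "aliases", "locus")
  genes <- genes[c(canon, setdiff(names(genes), canon))]
  rownames(genes) <- NULL
  structure(genes, species = species, class = c("genome_table", "data.frame"))
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table for", attr(x, "species"), "-", nrow(x), "genes on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
species_of <- function(table) attr(table, "species")

# restore the 0..n-1 order_index invariant, keeping the current ordering
# (existing, possibly fractional, order_index; row order when absent)
reindex_orders <- function(genes) {
  key <- genes$order_index
  if (is.null(key)) key <- seq_len(nrow(genes))
  genes$order_index <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    rows <- which(genes$chrom == ch)
    rows <- rows[order(key[rows])]
    genes$order_index[rows] <- seq_along(rows) - 1L
  }
  genes[order(genes$chrom, genes$order_index), , drop = FALSE]
}

rebuild_table <- function(genes, species) {
  genes <- reindex_orders(genes)
  rownames(genes) <- NULL
  structure(genes, species = species, class = c("genome_table", "data.frame"))
}

#' Load gene orders from GFF3 or BED
#'
#' Reads gene features and assigns `order_index` per chromosome by ascending
#' start, ties broken by ascending end then lexicographic gene id. GFF3's
#' 1-based closed coordinates are converted to the package's 0-based
#' half-open convention on load; BED is already 0-based half-open.
#'
#' @param file path to a GFF3 or BED file (or a character vector of lines).
#' @param species species label.
#' @param format "auto" (by extension), "gff3" or "bed".
#' @return a [genome_table()].
#' @export
load_gene_orders <- function(file, species, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (length(file) > 1 || !file.exists(file[1])) {
    tmp <- tempfile(fileext = if (format == "bed") ".bed" else ".gff3")
    writeLines(file, tmp)
    file <- tmp
  }
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", file, ignore.case = TRUE)) "bed" else "gff3"
  lines <- readLines(file)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) {
    return(genome_table(data.frame(gene_id = character(), chrom = character(),
                                   stringsAsFactors = FALSE), species))
  }
  nfield <- vapply(strsplit(lines[body], "\t"), length, integer(1))
  minf <- if (format == "gff3") 9L else 4L
  if (any(nfield < minf))
    stop(sprintf("load_gene_orders: malformed %s line %d (%d field(s), expected >= %d)",
                 format, body[which(nfield < minf)[1]], min(nfield), minf))
  gr <- rtracklayer::import(file, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    if (anyNA(ids)) stop("load_gene_orders: GFF3 gene feature without ID attribute")
    biotype <- if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype) else "protein_coding"
    biotype[is.na(biotype)] <- "protein_coding"
    aliases <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  } else {
    ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
           else sprintf("%s_gene%03d", as.character(GenomicRanges::seqnames(gr)), seq_along(gr))
    biotype <- "protein_coding"
    aliases <- NA_character_
  }
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"),
                    as.character(GenomicRanges::strand(gr)), NA_character_),
    biotype = biotype,
    aliases = aliases,
    stringsAsFactors = FALSE)
  genome_table(genes, species)
}

#' Write / read the package's genome-table TSV dialect
#'
#' Header: species, chrom, order_index, gene_id, start, end, strand, family,
#' biotype, placed, aliases, locus. Round-trips exactly.
#' @export
write_genome_tsv <- function(table, file) {
  df <- as.data.frame(table)
  df <- data.frame(species = species_of(table),
                   df[c("chrom", "order_index", "gene_id", "start", "end", "strand",
                        "family", "biotype", "placed", "aliases", "locus")],
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(file)
}

#' @rdname write_genome_tsv
#' @export
read_genome_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, na.strings = ".",
                          stringsAsFactors = FALSE, colClasses = "character")
  species <- unique(df$species)
  if (length(species) != 1) stop("read_genome_tsv: expected a single species per file")
  df$order_index <- as.integer(df$order_index)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$placed <- as.logical(df$placed)
  genome_table(df[setdiff(names(df), "species")], species)
}

#' Homology hits (BLAST outfmt-6 dialect)
#'
#' Reads the 12-column tab-separated BLAST `-outfmt 6` layout:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore.
#' @export
read_homology_tsv <- function(file) {
  cols <- c("query_gene", "subject_gene", "pct_identity", "aln_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bit_score")
  df <- utils::read.table(file, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("read_homology_tsv: expected 12 outfmt-6 columns, got ", ncol(df))
  df <- df[, 1:12]
  names(df) <- cols
  validate_hits(df)
  df
}

validate_hits <- function(hits) {
  stopifnot(all(c("query_gene", "subject_gene", "evalue", "bit_score") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("homology hits: negative E-value")
  if (!is.null(hits$pct_identity) &&
      any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("homology hits: pct_identity outside [0, 100]")
  if (any(!is.finite(hits$bit_score))) stop("homology hits: non-finite bit score")
  invisible(hits)
}

#' Filter homology hits on bit score and E-value
#'
#' Keeps hits with `bit_score > min_bit` AND `evalue < max_evalue` (both
#' strict), preserving input order. The defaults are the filter used for all
#' BLASTn-derived hit tables in this workflow.
#'
#' @param hits data.frame of hits (see [read_homology_tsv()]).
#' @param min_bit minimum bit score, exclusive. Default 40.
#' @param max_evalue maximum E-value, exclusive. Default 1e-4.
#' @export
filter_homology_hits <- function(hits, min_bit = 40, max_evalue = 1e-4) {
  validate_hits(hits)
  hits[hits$bit_score > min_bit & hits$evalue < max_evalue, , drop = FALSE]
}

#' Cluster filtered hits into homology families
#'
#' Single-linkage connected components over the undirected hit graph; each
#' component becomes a family labelled by its lexicographically smallest
#' member id. Genes listed in `universe` but touched by no hit become
#' singleton families.
#'
#' @param hits filtered hit table.
#' @param universe optional character vector of all gene ids.
#' @return named list (family label -> character vector of gene ids), class
#'   `homology_families`, with attribute `provenance = "clustered"`.
#' @export
build_families <- function(hits, universe = NULL) {
  edges <- unique(data.frame(a = pmin(hits$query_gene, hits$subject_gene),
                             b = pmax(hits$query_gene, hits$subject_gene),
                             stringsAsFactors = FALSE))
  verts <- sort(unique(c(edges$a, edges$b, universe)))
  if (!length(verts)) {
    return(structure(list(), provenance = "clustered", class = "homology_families"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  fams <- split(names(comp), comp)
  fams <- lapply(fams, sort)
  names(fams) <- vapply(fams, `[`, character(1), 1)
  fams <- fams[order(names(fams))]
  structure(fams, provenance = "clustered", class = "homology_families")
}

#' @export
print.homology_families <- function(x, ...) {
  cat(length(x), "homology families (", attr(x, "provenance"), ")\n")
  invisible(x)
}

# named vector gene_id -> family label
family_lookup <- function(families) {
  if (is.null(families)) return(NULL)
  if (inherits(families, "homology_families") || is.list(families)) {
    stats::setNames(rep(names(families), lengths(families)),
                    unlist(families, use.names = FALSE))
  } else families  # already a named vector
}

# family label for each gene in a table: explicit map > table's family column;
# unlabelled genes get an anonymous singleton label so they can never match.
gene_families <- function(table, families = NULL) {
  fam <- table$family
  lk <- family_lookup(families)
  if (!is.null(lk)) {
    hit <- table$gene_id %in% names(lk)
    fam[hit] <- unname(lk[table$gene_id[hit]])
  }
  anon <- is.na(fam)
  fam[anon] <- paste0("anon:", table$gene_id[anon])
  fam
}

#' Flanking protein-coding genes of a focus gene
#'
#' Up to `k` genes on each side of `gene_id` on its chromosome, nearest
#' first; non-protein-coding records are skipped unless `include_noncoding`.
#'
#' @return list(upstream =, downstream =) of `genome_table` row subsets.
#' @export
neighbors <- function(table, gene_id, k = 5, include_noncoding = FALSE) {
  stopifnot(k >= 1)
  row <- which(table$gene_id == gene_id)
  if (!length(row)) stop("neighbors: unknown gene '", gene_id, "'")
  chrom <- table$chrom[row]
  chr <- as.data.frame(table)[table$chrom == chrom, , drop = FALSE]
  chr <- chr[order(chr$order_index), , drop = FALSE]
  if (!include_noncoding)
    chr <- chr[chr$biotype == "protein_coding" | chr$gene_id == gene_id, , drop = FALSE]
  pos <- which(chr$gene_id == gene_id)
  up <- chr[rev(seq_len(pos - 1)), , drop = FALSE]   # nearest first
  down <- chr[pos + seq_len(nrow(chr) - pos), , drop = FALSE]
  list(upstream = utils::head(up, k), downstream = utils::head(down, k))
}
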