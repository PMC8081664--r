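#' Read a gene tree with supports and a leaf map
#'
#' Gene trees are inputs (inferred upstream by maximum likelihood or
#' TreeFam-style pipelines), never inferred here. Internal node labels are
#' treated as bootstrap percentages where numeric; values below
#' `low_support` are flagged as less informative.
#'
#' @param x Newick string, path, or `phylo`.
#' @param outgroup optional leaf label (or vector) to root on.
#' @export
read_gene_tree <- function(x, outgroup = NULL) {
  tree <- if (inherits(x, "phylo")) x
          else if (length(x) == 1 && file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
  if (is.null(tree)) stop("read_gene_tree: could not parse tree")
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Monophyly of synteny-defined orthogroups on a gene tree
#'
#' For each orthogroup with at least two mapped leaves, tests whether its
#' leaves form a clade; when they do not, reports the minimal set of leaves
#' whose removal restores monophyly (exact search up to `exact_max`
#' removals, greedy beyond, flagged), plus the bootstrap support at the
#' orthogroup's MRCA. Leaves missing from the map are excluded with a
#' warning - they cannot be scored.
#'
#' @param tree rooted gene tree (`phylo`, see [read_gene_tree()]).
#' @param leaf_map data.frame(leaf, species, orthogroup).
#' @param low_support bootstrap percentage under which support is flagged
#'   "less informative" (default 50).
#' @param exact_max maximum removal-set size searched exhaustively.
#' @return data.frame(orthogroup, n_leaves, monophyletic, violators,
#'   support, low_support, greedy).
#' @export
orthogroup_monophyly <- function(tree, leaf_map, low_support = 50, exact_max = 3) {
  unmapped <- setdiff(tree$tip.label, leaf_map$leaf)
  if (length(unmapped))
    warning("orthogroup_monophyly: unmapped leaves excluded: ",
            paste(unmapped, collapse = ", "))
  og_list <- split(leaf_map$leaf, leaf_map$orthogroup)
  og_list <- lapply(og_list, intersect, x0 <- tree$tip.label)
  og_list <- og_list[lengths(og_list) >= 2]
  support_at <- function(tr, leaves) {
    if (is.null(tr$node.label)) return(NA_real_)
    nd <- ape::getMRCA(tr, leaves)
    suppressWarnings(as.numeric(tr$node.label[nd - length(tr$tip.label)]))
  }
  mono <- function(tr, leaves) ape::is.monophyletic(tr, leaves)
  rows <- lapply(names(og_list), function(og) {
    leaves <- og_list[[og]]
    ok <- mono(tree, leaves)
    violators <- character()
    greedy <- FALSE
    if (!ok) {
      # candidates: own leaves + intruders inside the group's MRCA clade
      nd <- ape::getMRCA(tree, leaves)
      clade <- clade_leaves(tree, nd)
      cand <- union(leaves, setdiff(clade, leaves))
      found <- FALSE
      for (sz in seq_len(min(exact_max, length(cand) - 1))) {
        for (rm in utils::combn(cand, sz, simplify = FALSE)) {
          left <- setdiff(leaves, rm)
          if (length(left) < 2) next
          tr2 <- ape::drop.tip(tree, rm)
          if (mono(tr2, left)) { violators <- rm; found <- TRUE; break }
        }
        if (found) break
      }
      if (!found) {   # greedy: repeatedly drop the most intrusive leaf
        greedy <- TRUE
        tr2 <- tree; left <- leaves
        while (!mono(tr2, left)) {
          nd2 <- ape::getMRCA(tr2, left)
          intr <- setdiff(clade_leaves(tr2, nd2), left)
          drop1 <- if (length(intr)) intr[1] else left[1]
          violators <- c(violators, drop1)
          tr2 <- ape::drop.tip(tr2, drop1)
          left <- setdiff(left, drop1)
          if (length(left) < 2) break
        }
      }
    }
    sup <- support_at(tree, leaves)
    data.frame(orthogroup = og, n_leaves = length(leaves), monophyletic = ok,
               violators = paste(sort(violators), collapse = ";"),
               support = sup,
               low_support = !is.na(sup) && sup < low_support,
               greedy = greedy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Columns that diagnose two sequence groups
#'
#' Alignment columns where group A is fixed for one residue, group B fixed
#' for a different one - the sites that separate, e.g., the VTR1 and VTR2
#' receptor subfamilies. Columns containing gaps are excluded by default.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @param group_a,group_b names of the rows in each group.
#' @param exclude_gaps drop columns containing "-" in either group.
#' @return data.frame(column, residue_a, residue_b).
#' @export
diagnostic_sites <- function(alignment, group_a, group_b, exclude_gaps = TRUE) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("diagnostic_sites: ragged alignment")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  a <- m[group_a, , drop = FALSE]
  b <- m[group_b, , drop = FALSE]
  keep <- vapply(seq_len(ncol(m)), function(j) {
    ca <- unique(a[, j]); cb <- unique(b[, j])
    if (exclude_gaps && ("-" %in% ca || "-" %in% cb)) return(FALSE)
    length(ca) == 1 && length(cb) == 1 && ca != cb
  }, logical(1))
  data.frame(column = which(keep),
             residue_a = a[1, keep],
             residue_b = b[1, keep], stringsAsFactors = FALSE)
}

UNIVERSAL_NAMES <- c("OT", "VT", "OTR", "VTR1A", "VTR1B", "VTR2A", "VTR2B", "VTR2C")

#' Load the universal-nomenclature alias table
#'
#' Lineage-specific historical gene symbols mapped to the universal
#' vertebrate names (OT, VT, OTR, VTR1A, VTR1B, VTR2A, VTR2B, VTR2C). The
#' packaged table covers the common mammal/bird/reptile/frog/fish/shark
#' aliases; each (lineage, alias) pair must map to exactly one universal
#' name.
#'
#' @param path TSV with columns lineage, alias, universal; defaults to the
#'   packaged table.
#' @export
load_alias_table <- function(path = system.file("extdata", "table1_aliases.tsv",
                                                package = "paralogon")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          quote = "")
  stopifnot(all(c("lineage", "alias", "universal") %in% names(df)))
  bad <- setdiff(df$universal, UNIVERSAL_NAMES)
  if (length(bad)) stop("load_alias_table: unknown universal name(s): ",
                        paste(unique(bad), collapse = ", "))
  key <- paste(df$lineage, df$alias, sep = "\r")
  conf <- tapply(df$universal, key, function(u) length(unique(u)))
  if (any(conf > 1))
    stop("load_alias_table: conflicting mapping for ",
         paste(gsub("\r", "/", names(conf)[conf > 1]), collapse = ", "))
  df <- df[!duplicated(key), , drop = FALSE]
  class(df) <- c("alias_table", "data.frame")
  df
}

#' Rename lineage-specific gene symbols to universal names
#'
#' Matched aliases (case-insensitive) are replaced by their universal name;
#' names that already are universal pass through unchanged (idempotent);
#' anything else passes through and is listed as unmatched.
#'
#' @param names character vector of gene symbols.
#' @param lineage lineage the symbols come from (a `lineage` value of the
#'   alias table).
#' @param aliases an alias table ([load_alias_table()]).
#' @return list(renamed, report = data.frame(original, universal, status)).
#' @export
rename_genes <- function(names, lineage, aliases = load_alias_table()) {
  sub <- aliases[aliases$lineage == lineage, , drop = FALSE]
  lk <- stats::setNames(sub$universal, toupper(sub$alias))
  out <- character(length(names))
  status <- character(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    if (toupper(nm) %in% toupper(UNIVERSAL_NAMES)) {
      out[i] <- UNIVERSAL_NAMES[match(toupper(nm), toupper(UNIVERSAL_NAMES))]
      status[i] <- "already_universal"
    } else if (toupper(nm) %in% names(lk)) {
      out[i] <- unname(lk[toupper(nm)])
      status[i] <- "renamed"
    } else {
      out[i] <- nm
      status[i] <- "unmatched"
    }
  }
  list(renamed = out,
       report = data.frame(original = names, universal = out, status = status,
                           stringsAsFactors = FALSE))
}
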