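#' Write / read a scenario as JSON
#'
#' Schema: `tree` (Newick), `ancestor` (chromosome -> gene id array),
#' `canonical` (gene id -> class name), `events` (array of objects with
#' `kind`, `branch` and the payload fields of [event()]).
#' @export
write_scenario_json <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  obj <- list(
    tree = ape::write.tree(scn$tree),
    ancestor = scn$ancestor,
    canonical = as.list(scn$canonical %||% stats::setNames(list(), character())),
    events = lapply(scn$events, function(e) {
      e <- unclass(e)
      e$branch <- if (is.na(e$branch)) NULL else e$branch
      e
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  evs <- lapply(obj$events, function(e) {
    kind <- e$kind
    branch <- e$branch %||% NA_character_
    pay <- e[setdiff(names(e), c("kind", "branch"))]
    pay <- lapply(pay, function(v) if (is.list(v)) unlist(v) else v)
    do.call(event, c(list(kind = kind, branch = branch), pay))
  })
  canonical <- unlist(obj$canonical)
  ancestor <- lapply(obj$ancestor, function(ch) unlist(ch))
  scenario(obj$tree, ancestor, evs, canonical)
}

#' Write orthology calls / status matrices as TSV
#' @export
write_calls_tsv <- function(calls, file) {
  utils::write.table(as.data.frame(calls), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a presence/absence matrix in the 1/0/. dialect
#' @export
write_presence_matrix <- function(m, file) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
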