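# Readers and writers for the tabular formats the pipeline touches:
# disease characterization tables (TSV), gene-set databases (GMT), and
# protein-protein networks (two-column edge lists). All text is UTF-8,
# tab-delimited, with a header row where the format has one.

CLUSTER_LEVELS <- c("DB", "PB", "MPB", "UPB")
PROCESS_GROUPS <- 1:5
PROCESS_GROUP_NAMES <- c(
  `1` = "B cell-mediated",
  `2` = "T cell-mediated",
  `3` = "Innate immunity / inflammation",
  `4` = "Complement system",
  `5` = "Other"
)

#' Read a disease characterization table
#'
#' The table holds one disease per row: a stable identifier, the clinical
#' response cluster (`DB` definitely beneficial, `PB` probably beneficial,
#' `MPB` may provide benefit, `UPB` unlikely to provide benefit), the curated
#' pathophysiological processes as `group:label` entries separated by `;`
#' (group codes 1 B cell, 2 T cell, 3 innate immunity/inflammation,
#' 4 complement, 5 other), the number of effector proteins, and optionally the
#' effector identifiers themselves separated by `;`. Count-only tables (empty
#' `effectors` column) are valid: they carry the published per-disease counts
#' when the full effector lists are not distributed.
#'
#' @param path Path to a tab-separated file with columns `disease_id`, `name`,
#'   `cluster`, `processes`, `effector_count`, `effectors`.
#' @return A tibble with one row per disease; `processes` is a list-column of
#'   tibbles (`group`, `label`), `effectors` a list-column of character
#'   vectors, `cluster` a factor with levels DB, PB, MPB, UPB.
#' @seealso [write_disease_table()], [ivig_disease_panel()]
#' @export
read_disease_table <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("disease_id", "name", "cluster", "processes", "effector_count")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort_parse(sprintf("disease table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"effectors" %in% names(raw)) raw$effectors <- NA_character_
  recs <- purrr::pmap(
    list(raw$disease_id, raw$name, raw$cluster, raw$processes,
         raw$effector_count, raw$effectors, seq_len(nrow(raw))),
    parse_disease_row
  )
  out <- dplyr::bind_rows(recs)
  validate_disease_table(out)
  out
}

parse_disease_row <- function(disease_id, name, cluster, processes,
                              effector_count, effectors, row) {
  where <- sprintf("disease table row %d", row)
  if (is.na(disease_id) || !nzchar(trimws(disease_id))) {
    abort_parse(sprintf("%s: empty disease_id", where))
  }
  if (is.na(cluster) || !cluster %in% CLUSTER_LEVELS) {
    abort_validation(sprintf("%s: unknown response cluster '%s' (expected DB/PB/MPB/UPB)",
                             where, cluster))
  }
  if (is.na(processes) || !nzchar(trimws(processes))) {
    abort_validation(sprintf("%s: no pathophysiological processes", where))
  }
  entries <- trimws(strsplit(processes, ";", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  parsed <- stringr::str_match(entries, "^([0-9]+)\\s*:\\s*(.+)$")
  if (anyNA(parsed[, 1])) {
    abort_parse(sprintf("%s: malformed process entry '%s' (expected group:label)",
                        where, entries[which(is.na(parsed[, 1]))[1]]))
  }
  grp <- as.integer(parsed[, 2])
  if (any(!grp %in% PROCESS_GROUPS)) {
    abort_validation(sprintf("%s: process group %d outside 1-5", where,
                             grp[which(!grp %in% PROCESS_GROUPS)[1]]))
  }
  n_eff <- suppressWarnings(as.integer(effector_count))
  if (is.na(n_eff) || n_eff < 0) {
    abort_parse(sprintf("%s: effector_count '%s' is not a non-negative integer",
                        where, effector_count))
  }
  eff <- character(0)
  if (!is.na(effectors) && nzchar(trimws(effectors))) {
    eff <- normalize_protein(strsplit(effectors, ";", fixed = TRUE)[[1]])
    eff <- sort(unique(eff))
    if (length(eff) != n_eff) {
      abort_validation(sprintf("%s: effector_count %d != %d listed effectors",
                               where, n_eff, length(eff)))
    }
  }
  tibble::tibble(
    disease_id = trimws(disease_id),
    name = name,
    cluster = factor(cluster, levels = CLUSTER_LEVELS),
    processes = list(tibble::tibble(group = grp, label = parsed[, 3])),
    effectors = list(eff),
    effector_count = n_eff
  )
}

validate_disease_table <- function(diseases) {
  stopifnot(is.data.frame(diseases))
  dup <- diseases$disease_id[duplicated(diseases$disease_id)]
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate disease_id: %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- purrr::map_lgl(diseases$processes, ~ nrow(.x) == 0)
  if (any(bad)) abort_validation("disease with no processes")
  ok_count <- purrr::map2_lgl(diseases$effectors, diseases$effector_count,
                              ~ length(.x) == 0 || length(.x) == .y)
  if (!all(ok_count)) abort_validation("effector_count inconsistent with effector list")
  invisible(diseases)
}

#' Write a disease characterization table
#'
#' Inverse of [read_disease_table()]: the written file re-reads to a
#' content-identical table.
#'
#' @param diseases Disease tibble as returned by [read_disease_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_table <- function(diseases, path) {
  validate_disease_table(diseases)
  flat <- tibble::tibble(
    disease_id = diseases$disease_id,
    name = diseases$name,
    cluster = as.character(diseases$cluster),
    processes = purrr::map_chr(diseases$processes,
                               ~ paste(sprintf("%d:%s", .x$group, .x$label), collapse = ";")),
    effector_count = diseases$effector_count,
    effectors = purrr::map_chr(diseases$effectors, ~ paste(.x, collapse = ";"))
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-set database in GMT format
#'
#' Standard GMT: one gene set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are normalized
#' ([normalize_protein()]) and deduplicated. The test universe defaults to the
#' union of all members unless an explicit universe is supplied; universe
#' choice matters for the hypergeometric test and is deliberately exposed.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of protein identifiers to use as
#'   the enrichment universe; defaults to the union of all pathway members.
#' @return An object of class `pathway_db`: a list with `pathways` (named list
#'   of character vectors), `descriptions` (named character) and `universe`.
#' @export
read_gene_sets <- function(path, universe = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    rlang::warn("empty GMT file: returning an empty pathway database")
    return(new_pathway_db(list(), character(0), universe %||% character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort_validation(sprintf("GMT line %d has no members", bad[1]))
  }
  ids <- purrr::map_chr(fields, 1)
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate pathway id: %s", ids[duplicated(ids)][1]))
  }
  desc <- rlang::set_names(purrr::map_chr(fields, 2), ids)
  members <- rlang::set_names(
    purrr::map(fields, ~ sort(unique(normalize_protein(.x[-(1:2)])))), ids)
  new_pathway_db(members, desc, universe)
}

new_pathway_db <- function(pathways, descriptions, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathways, use.names = FALSE)))
  } else {
    universe <- sort(unique(normalize_protein(universe)))
  }
  outside <- setdiff(unlist(pathways, use.names = FALSE), universe)
  if (length(outside) > 0) {
    abort_validation(sprintf("%d pathway member(s) outside the supplied universe",
                             length(outside)))
  }
  structure(list(pathways = pathways, descriptions = descriptions,
                 universe = universe),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, universe of %d proteins\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Write a gene-set database in GMT format
#'
#' @param db A `pathway_db` from [read_gene_sets()] or [generate_pathway_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- purrr::imap_chr(db$pathways, function(members, id) {
    paste(c(id, db$descriptions[[id]] %||% "", members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction network from an edge list
#'
#' Each non-empty line is `idA<TAB>idB`. The network is undirected; duplicate
#' edges and self-loops are dropped (with a message reporting how many).
#'
#' @param path Path to a two-column tab-separated edge list (no header).
#' @return An undirected [igraph::igraph] whose vertex names are normalized
#'   protein identifiers.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    rlang::warn("empty edge list: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort_parse(sprintf("edge list line %d does not have exactly 2 columns", bad[1]))
  }
  a <- normalize_protein(purrr::map_chr(fields, 1))
  b <- normalize_protein(purrr::map_chr(fields, 2))
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- n_before - igraph::ecount(g)
  if (dropped > 0) {
    rlang::inform(sprintf("dropped %d duplicate edge(s)/self-loop(s)", dropped))
  }
  g
}

#' Write a network as a two-column edge list
#'
#' @param network An undirected [igraph::igraph] with named vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  # canonical order for byte-identical output
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  readr::write_lines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}
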