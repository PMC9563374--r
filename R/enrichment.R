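# Hypergeometric over-representation testing with Benjamini-Hochberg FDR
# control, and the Hausdorff-thresholded pathway similarity network.

#' Hypergeometric pathway enrichment
#'
#' Over-representation test of a query protein set against every pathway in a
#' database. With universe size \eqn{N}, pathway size \eqn{K}, effective query
#' size \eqn{n = |query \cap universe|} and overlap \eqn{k}, the p-value is the
#' upper tail \eqn{P(X \ge k)} of the hypergeometric distribution. Query
#' members outside the universe are dropped with a message.
#'
#' @param query Character vector of protein identifiers.
#' @param db A `pathway_db` (see [read_gene_sets()]).
#' @return A tibble sorted by ascending p-value with columns `pathway_id`,
#'   `description`, `k`, `n`, `K`, `N`, `p_value`.
#' @seealso [bh_correct()], [enrich()]
#' @export
hypergeometric_enrich <- function(query, db) {
  stopifnot(inherits(db, "pathway_db"))
  q <- unique(normalize_protein(query))
  eff <- intersect(q, db$universe)
  dropped <- length(q) - length(eff)
  if (dropped > 0) {
    rlang::inform(sprintf("%d query protein(s) outside the universe dropped", dropped))
  }
  if (length(eff) == 0) abort_validation("no query proteins in the universe")
  n <- length(eff)
  N <- length(db$universe)
  out <- tibble::tibble(
    pathway_id = names(db$pathways),
    description = unname(db$descriptions[names(db$pathways)]),
    K = unname(purrr::map_int(db$pathways, length)),
    k = unname(purrr::map_int(db$pathways, ~ length(intersect(.x, eff)))),
    n = n, N = N
  )
  # upper-tail P(X >= k) = P(X > k - 1)
  out$p_value <- stats::phyper(out$k - 1, out$K, out$N - out$K, out$n,
                               lower.tail = FALSE)
  out <- dplyr::relocate(out, "pathway_id", "description", "k", "n", "K", "N")
  dplyr::arrange(out, .data$p_value, .data$pathway_id)
}

#' Benjamini-Hochberg FDR correction
#'
#' Adds step-up adjusted q-values (`q_i = min_{j >= i} p_(j) m / j`, capped at
#' 1) and flags pathways significant at `q < alpha`.
#'
#' @param results Tibble from [hypergeometric_enrich()] (any tibble with a
#'   `p_value` column works).
#' @param alpha FDR threshold; default 0.05.
#' @return `results` with `q_value` and `significant` columns, sorted by
#'   ascending p-value.
#' @export
bh_correct <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), "p_value" %in% names(results))
  if (nrow(results) == 0) abort_validation("no enrichment results to correct")
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  results$significant <- results$q_value < alpha
  dplyr::arrange(results, .data$p_value)
}

#' Enrichment with FDR control in one call
#'
#' @inheritParams hypergeometric_enrich
#' @inheritParams bh_correct
#' @return See [bh_correct()].
#' @export
enrich <- function(query, db, alpha = 0.05) {
  bh_correct(hypergeometric_enrich(query, db), alpha = alpha)
}

# directed-max Hausdorff distance between two node sets over shortest-path
# hop distances; Inf when the sets live in different components.
hausdorff_hops <- function(dmat) {
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

#' Pathway similarity network at a Hausdorff-distance threshold
#'
#' Connects enriched pathways whose member sets are mutually close on the
#' protein network. The distance between pathways P and Q is the symmetric
#' Hausdorff distance over shortest-path hop counts,
#' \eqn{\max(\max_{p} \min_{q} d(p,q), \max_{q} \min_{p} d(p,q))};
#' an edge is drawn when the distance is strictly below `threshold`.
#' Under raw hop counts a threshold of 1 only connects pathways with
#' identical network coverage, so a normalized metric (hops divided by the
#' network diameter) is available via `metric = "normalized"`.
#'
#' @param enriched Tibble of enrichment results (typically the significant
#'   rows of [enrich()]) with a `pathway_id` column.
#' @param db The `pathway_db` the results came from.
#' @param network Protein network ([igraph::igraph]) used for distances.
#' @param threshold Strict upper bound for an edge; default 1.
#' @param metric `"hops"` (default) or `"normalized"`.
#' @return An object of class `pathway_graph`: list with `graph` (igraph),
#'   `edges` (tibble `from`, `to`, `distance`), `nodes`, `components`
#'   (membership tibble), `threshold`, `metric`.
#' @export
pathway_similarity_graph <- function(enriched, db, network, threshold = 1,
                                     metric = c("hops", "normalized")) {
  metric <- match.arg(metric)
  stopifnot(inherits(db, "pathway_db"))
  if (nrow(enriched) == 0) abort_validation("no enriched pathways supplied")
  ids <- enriched$pathway_id
  net_nodes <- igraph::V(network)$name
  mapped <- purrr::map(rlang::set_names(ids, ids), function(id) {
    mem <- db$pathways[[id]]
    kept <- intersect(mem, net_nodes)
    if (length(kept) < length(mem)) {
      rlang::inform(sprintf("pathway %s: %d member(s) not in the network dropped",
                            id, length(mem) - length(kept)))
    }
    kept
  })
  empty <- names(mapped)[lengths(mapped) == 0]
  if (length(empty) > 0) {
    rlang::warn(sprintf("excluding %d pathway(s) with no mapped members: %s",
                        length(empty), paste(empty, collapse = ", ")))
    mapped <- mapped[lengths(mapped) > 0]
  }
  ids <- names(mapped)
  if (length(ids) == 0) abort_validation("no pathway has members on the network")
  scale <- 1
  if (metric == "normalized") {
    scale <- igraph::diameter(network, directed = FALSE)
    if (scale == 0) scale <- 1
  }
  pairs <- if (length(ids) >= 2) utils::combn(ids, 2, simplify = FALSE) else list()
  edges <- purrr::map(pairs, function(p) {
    dmat <- igraph::distances(network, v = mapped[[p[1]]], to = mapped[[p[2]]])
    d <- hausdorff_hops(dmat) / scale
    tibble::tibble(from = p[1], to = p[2], distance = d)
  })
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0),
                            distance = numeric(0))
  }
  kept <- edges[is.finite(edges$distance) & edges$distance < threshold, ]
  g <- igraph::graph_from_data_frame(kept[, c("from", "to")], directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)
  structure(list(
    graph = g,
    edges = kept,
    all_distances = edges,
    nodes = ids,
    components = tibble::tibble(pathway_id = names(comp$membership),
                                component = unname(comp$membership)),
    threshold = threshold,
    metric = metric
  ), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d pathways, %d edges (%s distance < %g), %d component(s)\n",
              length(x$nodes), nrow(x$edges), x$metric, x$threshold,
              max(x$components$component)))
  invisible(x)
}
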