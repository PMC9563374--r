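# Process-group frequency per response cluster, and the chi-squared
# dependence analysis between process groups and cluster membership.

# cluster x group presence-count matrix: a disease counts once per group
# regardless of how many of its processes carry that group.
presence_counts <- function(diseases) {
  validate_disease_table(diseases)
  present <- purrr::map(diseases$processes, ~ sort(unique(.x$group)))
  long <- tibble::tibble(
    cluster = rep(diseases$cluster, lengths(present)),
    group = unlist(present)
  )
  clusters <- levels(droplevels(diseases$cluster))
  tab <- table(factor(as.character(long$cluster), levels = clusters),
               factor(long$group, levels = PROCESS_GROUPS))
  counts <- matrix(as.integer(tab), nrow = length(clusters),
                   dimnames = list(clusters, as.character(PROCESS_GROUPS)))
  totals <- table(factor(diseases$cluster, levels = clusters))
  list(counts = counts, totals = as.integer(totals), clusters = clusters)
}

#' Frequency of process groups per response cluster
#'
#' For each response cluster and immune-system process group (1 B cell,
#' 2 T cell, 3 innate immunity/inflammation, 4 complement, 5 other), the
#' percentage of the cluster's diseases annotated with at least one process of
#' that group. A disease counts once per group however many of its processes
#' carry it.
#'
#' @param diseases Disease tibble (see [read_disease_table()]).
#' @return A tibble of class `ivig_freq` with columns `cluster`, `group`,
#'   `group_name`, `n_diseases`, `cluster_total`, `frequency_pct`.
#' @examples
#' build_frequency_table(ivig_disease_panel())
#' @export
build_frequency_table <- function(diseases) {
  if (nrow(diseases) == 0) abort_validation("empty disease table")
  pc <- presence_counts(diseases)
  out <- tidyr::expand_grid(cluster = pc$clusters, group = PROCESS_GROUPS)
  out$n_diseases <- pc$counts[cbind(out$cluster, as.character(out$group))]
  out$cluster_total <- pc$totals[match(out$cluster, pc$clusters)]
  out$frequency_pct <- 100 * out$n_diseases / out$cluster_total
  out$group_name <- unname(PROCESS_GROUP_NAMES[as.character(out$group)])
  out$cluster <- factor(out$cluster, levels = CLUSTER_LEVELS)
  out <- dplyr::relocate(out, "cluster", "group", "group_name")
  class(out) <- c("ivig_freq", class(out))
  out
}

#' Chi-squared dependence between process groups and response clusters
#'
#' Tests independence between cluster membership and process-group presence.
#' The overall statistic is Pearson's chi-squared on the cluster-by-group
#' presence-count table with `(n_clusters - 1) * (n_groups - 1)` degrees of
#' freedom. Because the published figure marks individual cells without
#' stating a per-cell method, each cell additionally gets a 2x2 chi-squared of
#' (this cluster vs the rest) x (group present vs absent) over diseases,
#' without continuity correction; per-cell tests are uncorrected by default,
#' with optional Benjamini-Hochberg adjustment via `cell_fdr`.
#'
#' @param diseases Disease tibble.
#' @param alpha Per-cell significance level (default 0.05).
#' @param cell_fdr If `TRUE`, apply Benjamini-Hochberg correction to the
#'   per-cell p-values before flagging.
#' @return An object of class `ivig_chisq`: list with `statistic`, `dof`,
#'   `p_value`, `observed`, `expected`, and `cells` (tibble with per-cell
#'   statistic, p-value and significance flag).
#' @export
test_independence <- function(diseases, alpha = 0.05, cell_fdr = FALSE) {
  pc <- presence_counts(diseases)
  counts <- pc$counts
  keep_rows <- rowSums(counts) > 0
  keep_cols <- colSums(counts) > 0
  if (!all(keep_rows) || !all(keep_cols)) {
    rlang::warn("dropping zero row(s)/column(s) from the presence table before testing")
    counts <- counts[keep_rows, keep_cols, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort_validation("need at least 2 clusters and 2 process groups to test independence")
  }
  overall <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))

  # per-cell 2x2 partitions over diseases
  clusters <- rownames(counts)
  groups <- as.integer(colnames(counts))
  has_group <- purrr::map(diseases$processes, ~ unique(.x$group))
  cells <- tidyr::expand_grid(cluster = clusters, group = groups)
  cell_stats <- purrr::pmap(cells, function(cluster, group) {
    in_cl <- diseases$cluster == cluster
    in_gr <- purrr::map_lgl(has_group, ~ group %in% .x)
    tab <- table(factor(in_cl, levels = c(TRUE, FALSE)),
                 factor(in_gr, levels = c(TRUE, FALSE)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    # a constant margin yields NaN; treat as no evidence against independence
    list(statistic = ifelse(is.nan(ct$statistic), 0, unname(ct$statistic)),
         p_value = ifelse(is.nan(ct$p.value), 1, ct$p.value))
  })
  cells$statistic <- purrr::map_dbl(cell_stats, "statistic")
  cells$p_value <- purrr::map_dbl(cell_stats, "p_value")
  p_flag <- if (cell_fdr) stats::p.adjust(cells$p_value, method = "BH") else cells$p_value
  cells$q_value <- if (cell_fdr) p_flag else NA_real_
  cells$significant <- p_flag < alpha

  structure(list(
    statistic = unname(overall$statistic),
    dof = unname(overall$parameter),
    p_value = overall$p.value,
    observed = counts,
    expected = overall$expected,
    cells = cells,
    alpha = alpha,
    cell_fdr = cell_fdr
  ), class = "ivig_chisq")
}

#' @export
print.ivig_chisq <- function(x, ...) {
  cat(sprintf("Chi-squared dependence test: X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  cat(sprintf("%d/%d cells flagged at alpha = %g%s\n",
              sum(x$cells$significant), nrow(x$cells), x$alpha,
              if (x$cell_fdr) " (BH-corrected)" else ""))
  invisible(x)
}

#' @rdname test_independence
#' @param x An `ivig_chisq` object.
#' @param ... Unused.
#' @method tidy ivig_chisq
#' @export
tidy.ivig_chisq <- function(x, ...) {
  x$cells
}

#' @rdname test_independence
#' @method glance ivig_chisq
#' @export
glance.ivig_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$dof, p.value = x$p_value,
                 n_cells_significant = sum(x$cells$significant))
}
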