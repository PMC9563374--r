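# End-to-end orchestration: characterization load/generation, cluster
# statistics, set analysis, enrichment, and ensemble training/scoring,
# with a machine-readable report that is a pure function of (inputs, seed).

#' Pipeline run configuration
#'
#' Exactly one input mode must be active: either explicit file paths
#' (`disease_table`, `network`, `gene_sets`) or a [synthetic_config()] block.
#' All thresholds used downstream live here so every number in the report
#' traces back to the configuration.
#'
#' @param disease_table,network,gene_sets Paths to a disease table (TSV), an
#'   edge list (TSV) and a gene-set database (GMT); all three are required in
#'   file mode.
#' @param synthetic A [synthetic_config()] for fully synthetic runs.
#' @param seed Master seed for every random stage.
#' @param ensemble An [ensemble_config()]; its seed is overridden by `seed`.
#' @param enrichment_alpha FDR threshold for enrichment significance.
#' @param score_cutoffs,p_cutoffs Relationship-category boundaries
#'   (see [score_category()]).
#' @param hausdorff_threshold Strict distance bound for the pathway graph.
#' @param hausdorff_metric `"hops"` or `"normalized"` (see
#'   [pathway_similarity_graph()]).
#' @param train_fraction,calibration_fraction Fractions of the labeled pairs
#'   used for training and calibration; the remainder is held out for
#'   evaluation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(disease_table = NULL, network = NULL, gene_sets = NULL,
                       synthetic = NULL, seed = 1L,
                       ensemble = ensemble_config(),
                       enrichment_alpha = 0.05,
                       score_cutoffs = c(78, 71, 38),
                       p_cutoffs = c(0.05, 0.1, 0.25),
                       hausdorff_threshold = 1,
                       hausdorff_metric = "hops",
                       train_fraction = 0.6,
                       calibration_fraction = 0.2) {
  file_mode <- !is.null(disease_table) || !is.null(network) || !is.null(gene_sets)
  synth_mode <- !is.null(synthetic)
  if (file_mode && synth_mode) {
    abort_config("supply either file inputs or a synthetic block, not both")
  }
  if (!file_mode && !synth_mode) {
    abort_config("one of file inputs or a synthetic block is required")
  }
  if (file_mode && (is.null(disease_table) || is.null(network) || is.null(gene_sets))) {
    abort_config("file mode needs disease_table, network and gene_sets paths")
  }
  if (synth_mode) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    synthetic$seed <- as.integer(seed)
  }
  ensemble$seed <- as.integer(seed)
  if (train_fraction + calibration_fraction >= 1) {
    abort_config("train_fraction + calibration_fraction must leave a held-out test set")
  }
  structure(list(
    disease_table = disease_table, network = network, gene_sets = gene_sets,
    synthetic = synthetic, seed = as.integer(seed), ensemble = ensemble,
    enrichment_alpha = enrichment_alpha, score_cutoffs = score_cutoffs,
    p_cutoffs = p_cutoffs, hausdorff_threshold = hausdorff_threshold,
    hausdorff_metric = hausdorff_metric,
    train_fraction = train_fraction, calibration_fraction = calibration_fraction
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: characterization load/generation, process-group
#' cluster statistics, protein-overlap set analysis, pathway enrichment of
#' the DB-without-UPB / only-DB / only-UPB compartments, and ensemble
#' training, calibration, evaluation and pair scoring. The machine-readable
#' report is deterministic for a fixed configuration and seed (no
#' timestamps).
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, the report is written as
#'   `report.json` plus a human-readable `summary.txt`.
#' @return A list of class `ivig_report` with one block per stage, the seed
#'   and a configuration hash.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  synth <- !is.null(config$synthetic)

  # -- stage 1: characterization -------------------------------------------
  if (synth) {
    network <- generate_network(config$synthetic)
    diseases <- generate_disease_panel(config$synthetic, network)
    pathway_db <- generate_pathway_db(config$synthetic, network, diseases)
    pairs <- generate_training_pairs(config$synthetic, network, diseases)
  } else {
    diseases <- read_disease_table(config$disease_table)
    network <- read_network(config$network)
    pathway_db <- read_gene_sets(config$gene_sets)
    pairs <- NULL
  }
  network <- cache_diameter(network)
  have_effectors <- all(purrr::map_int(diseases$effectors, length) > 0)
  stage_characterization <- list(
    n_diseases = nrow(diseases),
    n_per_cluster = as.list(table(diseases$cluster)),
    n_network_nodes = igraph::vcount(network),
    n_network_edges = igraph::ecount(network),
    n_pathways = length(pathway_db$pathways),
    effectors_available = have_effectors
  )

  # -- stage 2: cluster statistics -----------------------------------------
  freq <- build_frequency_table(diseases)
  indep <- test_independence(diseases)
  stage_cluster_stats <- list(
    frequency = as.data.frame(freq),
    chisq = list(statistic = indep$statistic, dof = indep$dof,
                 p_value = indep$p_value),
    cells = as.data.frame(indep$cells)
  )

  # -- stage 3: set analysis ------------------------------------------------
  if (have_effectors) {
    unions <- cluster_unions(diseases)
    sims <- pairwise_similarity(unions)
    tree <- build_similarity_tree(unions)
    venn <- venn_partition(unions$DB, unions$PB, unions$MPB, unions$UPB)
    stage_set_analysis <- list(
      union_sizes = purrr::map_int(unions, length),
      pairwise = as.data.frame(sims),
      tree_merges = as.data.frame(tree$merges),
      newick = tree$newick,
      venn_sizes = as.list(venn$sizes)
    )
  } else {
    venn <- NULL
    stage_set_analysis <- list(skipped = "disease table is count-only (no effector lists)")
  }

  # -- stage 4: enrichment --------------------------------------------------
  if (have_effectors) {
    compartments <- list(db_without_upb = venn$db_without_upb,
                         only_db = venn$only_db, only_upb = venn$only_upb)
    enr <- purrr::map(compartments, function(q) {
      if (length(intersect(normalize_protein(q), pathway_db$universe)) == 0) {
        return(NULL)
      }
      enrich(q, pathway_db, alpha = config$enrichment_alpha)
    })
    sig <- purrr::map(enr, ~ if (is.null(.x)) NULL else .x[.x$significant, ])
    pg <- NULL
    if (!is.null(sig$db_without_upb) && nrow(sig$db_without_upb) > 0) {
      pg <- pathway_similarity_graph(sig$db_without_upb, pathway_db, network,
                                     threshold = config$hausdorff_threshold,
                                     metric = config$hausdorff_metric)
    }
    stage_enrichment <- list(
      n_significant = purrr::map(enr, ~ if (is.null(.x)) 0L else sum(.x$significant)),
      results = purrr::map(enr, ~ if (is.null(.x)) NULL else as.data.frame(.x)),
      pathway_graph = if (is.null(pg)) NULL else list(
        n_nodes = length(pg$nodes), n_edges = nrow(pg$edges),
        n_components = max(pg$components$component))
    )
  } else {
    stage_enrichment <- list(skipped = "no effector lists available")
  }

  # -- stage 5: ensemble ----------------------------------------------------
  if (!is.null(pairs)) {
    split <- split_pairs(pairs, config$train_fraction,
                         config$calibration_fraction, config$seed)
    model <- train_ensemble(split$train, network, config$ensemble)
    model <- calibrate(model, split$calibration, network)
    ev <- evaluate_ensemble(model, split$test, network)
    scored <- ev$scored
    scored$category <- score_category(scored$score, scored$p_value,
                                      config$score_cutoffs, config$p_cutoffs)
    stage_ann <- list(
      n_train = nrow(split$train), n_calibration = nrow(split$calibration),
      n_test = nrow(split$test),
      accuracy = ev$accuracy, auc = ev$auc,
      per_stratum = as.data.frame(ev$per_stratum),
      category_counts = as.list(table(scored$category)),
      scored_pairs = as.data.frame(
        scored[, c("pair_id", "drug_id", "disease_id", "label",
                   "score", "p_value", "stratum")])
    )
  } else {
    stage_ann <- list(skipped = "no labeled drug-indication pairs supplied")
  }

  report <- structure(list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages = list(
      characterization = stage_characterization,
      cluster_stats = stage_cluster_stats,
      set_analysis = stage_set_analysis,
      enrichment = stage_enrichment,
      ann = stage_ann
    )
  ), class = "ivig_report")

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# deterministic train/calibration/test split, stratified by label
split_pairs <- function(pairs, train_fraction, calibration_fraction, seed) {
  withr::with_seed(sub_seed(seed, "split"), {
    idx <- sample(nrow(pairs))
    n_train <- floor(train_fraction * nrow(pairs))
    n_cal <- floor(calibration_fraction * nrow(pairs))
    list(
      train = pairs[sort(idx[seq_len(n_train)]), ],
      calibration = pairs[sort(idx[n_train + seq_len(n_cal)]), ],
      test = pairs[sort(idx[-seq_len(n_train + n_cal)]), ]
    )
  })
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable, deterministic) and `summary.txt`.
#'
#' @param report An `ivig_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ivig_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  summary_path <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), summary_path)
  invisible(json_path)
}

#' @export
print.ivig_report <- function(x, ...) {
  cat("IVIg network-analysis pipeline report\n")
  cat(sprintf("seed %d, config %s\n", x$seed, x$config_hash))
  st <- x$stages
  cat(sprintf("1. characterization: %d diseases, %d-node network, %d pathways\n",
              st$characterization$n_diseases, st$characterization$n_network_nodes,
              st$characterization$n_pathways))
  cat(sprintf("2. cluster stats: X2 = %.2f (df %d, p = %.3g)\n",
              st$cluster_stats$chisq$statistic, st$cluster_stats$chisq$dof,
              st$cluster_stats$chisq$p_value))
  if (!is.null(st$set_analysis$skipped)) {
    cat(sprintf("3. set analysis: skipped (%s)\n", st$set_analysis$skipped))
  } else {
    cat(sprintf("3. set analysis: venn sizes %s\n",
                paste(names(st$set_analysis$venn_sizes),
                      unlist(st$set_analysis$venn_sizes), sep = "=", collapse = ", ")))
  }
  if (!is.null(st$enrichment$skipped)) {
    cat(sprintf("4. enrichment: skipped (%s)\n", st$enrichment$skipped))
  } else {
    cat(sprintf("4. enrichment: significant pathways %s\n",
                paste(names(st$enrichment$n_significant),
                      unlist(st$enrichment$n_significant), sep = "=", collapse = ", ")))
  }
  if (!is.null(st$ann$skipped)) {
    cat(sprintf("5. ensemble: skipped (%s)\n", st$ann$skipped))
  } else {
    cat(sprintf("5. ensemble: held-out accuracy %.3f, AUC %.3f (n = %d)\n",
                st$ann$accuracy, st$ann$auc, st$ann$n_test))
  }
  invisible(x)
}
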