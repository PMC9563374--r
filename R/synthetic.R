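# Seeded generators for offline benchmarking: a scale-free protein network,
# a disease panel with the cluster/process dependency structure of the real
# panel, drug-indication training pairs with a planted topological signal,
# and a pathway database with planted and decoy sets. Every generator is a
# pure function of (config, seed): repeated calls give identical output.

#' Configuration for the synthetic-data generators
#'
#' Defaults define the package's reference benchmark conditions: a 300-node
#' preferential-attachment network, a 26-disease panel split 7/6/9/4 across
#' the DB/PB/MPB/UPB response clusters (matching the published panel), 400
#' drug-indication pairs at 50% positives, and a 2-hop proximity radius
#' separating mechanistically related from unrelated target sets.
#'
#' @param seed Master seed; every sub-generator derives its own stream from it.
#' @param n_nodes Number of network proteins.
#' @param attachment_m Edges added per node during preferential attachment.
#' @param n_pathways Number of pathways (half planted around disease
#'   neighborhoods, half uniform decoys).
#' @param pathway_size_range `c(min, max)` pathway sizes.
#' @param target_count_range `c(min, max)` drug target-set sizes.
#' @param n_diseases_per_cluster Named integer vector over DB/PB/MPB/UPB.
#' @param effector_count_range `c(min, max)` effector-set sizes.
#' @param proximity_radius Graph hops within which positive-pair targets are
#'   sampled; negatives sit at least `proximity_radius + 2` hops away.
#' @param positive_fraction Fraction of related pairs among `n_pairs`.
#' @param n_pairs Total drug-indication pairs generated.
#' @param noise_fraction Fraction of each effector set drawn uniformly at
#'   random rather than from the seeded neighborhood.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_nodes = 300L,
                             attachment_m = 1L,
                             n_pathways = 50L,
                             pathway_size_range = c(8L, 40L),
                             target_count_range = c(1L, 12L),
                             n_diseases_per_cluster = c(DB = 7L, PB = 6L, MPB = 9L, UPB = 4L),
                             effector_count_range = c(15L, 60L),
                             proximity_radius = 2L,
                             positive_fraction = 0.5,
                             n_pairs = 400L,
                             noise_fraction = 0.1) {
  check_range(pathway_size_range, "pathway_size_range")
  check_range(target_count_range, "target_count_range")
  check_range(effector_count_range, "effector_count_range")
  if (n_nodes < attachment_m + 1) {
    abort_config("n_nodes must be at least attachment_m + 1")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    abort_config("positive_fraction must lie in (0, 1)")
  }
  if (proximity_radius < 0) abort_config("proximity_radius must be non-negative")
  if (!all(CLUSTER_LEVELS %in% names(n_diseases_per_cluster))) {
    abort_config("n_diseases_per_cluster must name DB, PB, MPB and UPB")
  }
  if (effector_count_range[2] > n_nodes) {
    abort_config("effector_count_range exceeds the number of network nodes")
  }
  structure(list(
    seed = as.integer(seed), n_nodes = as.integer(n_nodes),
    attachment_m = as.integer(attachment_m), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    target_count_range = as.integer(target_count_range),
    n_diseases_per_cluster = n_diseases_per_cluster,
    effector_count_range = as.integer(effector_count_range),
    proximity_radius = as.integer(proximity_radius),
    positive_fraction = positive_fraction,
    n_pairs = as.integer(n_pairs),
    noise_fraction = noise_fraction
  ), class = "synthetic_config")
}

#' Generate a synthetic scale-free protein network
#'
#' Preferential-attachment (Barabasi-Albert) growth, giving the heavy-tailed
#' degree distribution typical of protein interactomes. The graph is connected
#' by construction and deterministic for a fixed config seed.
#'
#' @param config A [synthetic_config()].
#' @return An undirected [igraph::igraph] with vertex names `P0001`, ...
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- withr::with_seed(sub_seed(config$seed, "network"), {
    igraph::sample_pa(config$n_nodes, m = config$attachment_m, directed = FALSE)
  })
  igraph::V(g)$name <- sprintf("P%04d", seq_len(config$n_nodes))
  g
}

# Sample an effector-like node set: a connected ball around a seed node plus
# a small uniform-noise admixture. Runs inside an active RNG stream.
sample_neighborhood_set <- function(network, size, radius, noise_fraction) {
  nodes <- igraph::V(network)$name
  seed_node <- sample(nodes, 1)
  ball <- ball_around(network, seed_node, radius)
  r <- radius
  while (length(ball) < size && r < igraph::vcount(network)) {
    r <- r + 1
    ball <- ball_around(network, seed_node, r)
  }
  n_noise <- min(floor(size * noise_fraction), length(setdiff(nodes, ball)))
  core <- sample(ball, size - n_noise)
  noise <- sample(setdiff(nodes, ball), n_noise)
  sort(unique(c(core, noise)))
}

ball_around <- function(network, centers, radius) {
  hood <- igraph::ego(network, order = radius, nodes = centers)
  sort(unique(unlist(purrr::map(hood, ~ .x$name))))
}

# process-label vocabulary used by the panel generator
SYNTH_PROCESS_LABELS <- c(
  `1` = "Dysregulated B cell response",
  `2` = "T cell-mediated response",
  `3` = "Exaggerated innate immune response",
  `4` = "Complement system",
  `5` = "Tissue-specific dysfunction"
)

#' Generate a synthetic disease panel
#'
#' Emulates the structure of the curated panel: diseases per response cluster
#' as configured; every DB disease carries process groups 1 (B cell) and 4
#' (complement), and every MPB and UPB disease carries group 3 (innate
#' immunity/inflammation), mirroring the dependency pattern seen in the real
#' panel; remaining groups are added at random. Effector sets are connected
#' graph neighborhoods (ball of `proximity_radius` hops around a random seed
#' node) with a uniform-noise admixture.
#'
#' @param config A [synthetic_config()].
#' @param network Network from [generate_network()].
#' @return A disease tibble (same shape as [read_disease_table()]).
#' @export
generate_disease_panel <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"))
  if (igraph::vcount(network) == 0) abort_config("network is empty")
  if (config$effector_count_range[2] > igraph::vcount(network)) {
    abort_config("effector_count_range exceeds the number of network nodes")
  }
  counts <- config$n_diseases_per_cluster[CLUSTER_LEVELS]
  if (sum(counts) == 0) {
    rlang::warn("all cluster counts are zero: returning an empty panel")
    return(tibble::tibble(disease_id = character(0), name = character(0),
                          cluster = factor(character(0), levels = CLUSTER_LEVELS),
                          processes = list(), effectors = list(),
                          effector_count = integer(0)))
  }
  withr::with_seed(sub_seed(config$seed, "panel"), {
    rows <- purrr::imap(counts, function(n, cl) {
      if (n == 0) return(NULL)
      purrr::map(seq_len(n), function(i) {
        guaranteed <- switch(cl, DB = c(1L, 4L), MPB = 3L, UPB = 3L, integer(0))
        extra <- sample(setdiff(PROCESS_GROUPS, guaranteed),
                        size = sample.int(3, 1))
        grp <- c(guaranteed, extra)
        size <- sample(seq(config$effector_count_range[1],
                           config$effector_count_range[2]), 1)
        eff <- sample_neighborhood_set(network, size, config$proximity_radius,
                                       config$noise_fraction)
        tibble::tibble(
          disease_id = sprintf("%s_%02d", cl, i),
          name = sprintf("synthetic %s condition %d", cl, i),
          cluster = factor(cl, levels = CLUSTER_LEVELS),
          processes = list(tibble::tibble(group = grp,
                                          label = unname(SYNTH_PROCESS_LABELS[as.character(grp)]))),
          effectors = list(eff),
          effector_count = length(eff)
        )
      })
    })
    out <- dplyr::bind_rows(purrr::flatten(rows))
    validate_disease_table(out)
    out
  })
}

#' Generate labeled drug-indication training pairs
#'
#' Positives pair a disease with a pseudo-drug whose targets are sampled
#' within `proximity_radius` hops of the disease's effector neighborhood;
#' negatives sample targets from nodes at least `proximity_radius + 2` hops
#' away from every effector of the paired disease. This plants a learnable
#' topological signal: mechanistically related target sets are close to the
#' disease effectors on the network, unrelated ones are not. Target-set sizes
#' span `target_count_range` so size stratification is exercised.
#'
#' @param config A [synthetic_config()].
#' @param network Network from [generate_network()].
#' @param diseases Disease panel with non-empty effector sets.
#' @return A tibble with columns `pair_id`, `drug_id`, `disease_id`,
#'   `targets` (list of character), `effectors` (list of character),
#'   `label` (factor related/unrelated).
#' @export
generate_training_pairs <- function(config, network, diseases) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(purrr::map_int(diseases$effectors, length) == 0)) {
    abort_config("diseases must have non-empty effector sets")
  }
  n_pos <- round(config$n_pairs * config$positive_fraction)
  n_neg <- config$n_pairs - n_pos
  nodes <- igraph::V(network)$name
  withr::with_seed(sub_seed(config$seed, "pairs"), {
    # per-disease near/far node pools
    pools <- purrr::map(diseases$effectors, function(eff) {
      near <- ball_around(network, eff, config$proximity_radius)
      d <- igraph::distances(network, v = eff, to = nodes)
      min_d <- apply(d, 2, min)
      far <- nodes[min_d >= config$proximity_radius + 2]
      list(near = near, far = far)
    })
    too_small <- purrr::map_lgl(pools, ~ length(.x$far) < config$target_count_range[2])
    if (all(too_small)) {
      abort_config("network too small to place negatives at the required separation")
    }
    make_pair <- function(i, positive) {
      repeat {
        di <- sample(nrow(diseases), 1)
        pool <- if (positive) pools[[di]]$near else pools[[di]]$far
        k_max <- min(config$target_count_range[2], length(pool))
        if (k_max >= config$target_count_range[1]) break
      }
      k <- sample(seq(config$target_count_range[1], k_max), 1)
      tibble::tibble(
        drug_id = sprintf("%s_%04d", if (positive) "POSDRUG" else "NEGDRUG", i),
        disease_id = diseases$disease_id[di],
        targets = list(sort(sample(pool, k))),
        effectors = diseases$effectors[di],
        label = factor(if (positive) "related" else "unrelated",
                       levels = c("related", "unrelated"))
      )
    }
    out <- dplyr::bind_rows(
      purrr::map(seq_len(n_pos), make_pair, positive = TRUE),
      purrr::map(seq_len(n_neg), make_pair, positive = FALSE)
    )
    out$pair_id <- seq_len(nrow(out))
    dplyr::relocate(out, "pair_id")
  })
}

#' Generate a synthetic pathway database
#'
#' Half of the pathways are planted as graph neighborhoods around the effector
#' sets of the supplied diseases (so they genuinely overlap disease biology);
#' the other half are uniform-random decoys. The universe is the full node
#' set of the network.
#'
#' @param config A [synthetic_config()].
#' @param network Network from [generate_network()].
#' @param diseases Disease panel with non-empty effector sets.
#' @return A `pathway_db`; planted pathways are named `PLANTED_*`, decoys
#'   `DECOY_*`.
#' @export
generate_pathway_db <- function(config, network, diseases) {
  stopifnot(inherits(config, "synthetic_config"))
  nodes <- igraph::V(network)$name
  n_planted <- ceiling(config$n_pathways / 2)
  n_decoy <- config$n_pathways - n_planted
  withr::with_seed(sub_seed(config$seed, "pathways"), {
    planted <- purrr::map(seq_len(n_planted), function(i) {
      di <- sample(nrow(diseases), 1)
      eff <- diseases$effectors[[di]]
      anchor <- sample(eff, 1)
      size <- sample(seq(config$pathway_size_range[1],
                         config$pathway_size_range[2]), 1)
      ball <- ball_around(network, anchor, config$proximity_radius)
      # keep the pathway anchored in the disease neighborhood
      pool <- union(ball, eff)
      sort(sample(pool, min(size, length(pool))))
    })
    decoy <- purrr::map(seq_len(n_decoy), function(i) {
      size <- sample(seq(config$pathway_size_range[1],
                         config$pathway_size_range[2]), 1)
      sort(sample(nodes, size))
    })
    pathways <- c(
      rlang::set_names(planted, sprintf("PLANTED_%03d", seq_len(n_planted))),
      rlang::set_names(decoy, sprintf("DECOY_%03d", seq_len(n_decoy)))
    )
    desc <- rlang::set_names(
      c(rep("planted disease-neighborhood pathway", n_planted),
        rep("uniform decoy pathway", n_decoy)),
      names(pathways))
    new_pathway_db(pathways, desc, universe = nodes)
  })
}
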