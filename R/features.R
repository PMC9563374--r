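# Topological feature extraction: how a drug's target set sits relative to a
# disease's effector set on the protein network. These nine features feed the
# ensemble classifier; they capture proximity (hop distances, random-walk
# reachability), overlap, and set/degree size effects.

FEATURE_NAMES <- c(
  "min_hop", "mean_min_hop", "median_min_hop", "frac_within_2", "jaccard",
  "log_n_targets", "log_n_effectors", "log_mean_target_degree", "rw_proximity"
)

#' Topological features from a target set to an effector set
#'
#' Computes, over the protein network: the minimum hop distance from any
#' target to any effector; the mean and median over targets of each target's
#' minimum distance to the effector set; the fraction of targets within 2
#' hops; the Jaccard overlap of the two sets; log-scaled target count,
#' effector count and mean target degree; and a random-walk proximity (a
#' personalized PageRank with restart probability 0.15 on the effector set,
#' summed over the targets). Pairs in disconnected components get their
#' infinite hop distances imputed as network diameter + 1, so every feature is
#' finite. Identifiers absent from the network are dropped with a message;
#' if no target or no effector maps, an error is raised.
#'
#' @param network Protein network ([igraph::igraph]) with named vertices.
#' @param targets,effectors Character vectors of protein identifiers.
#' @return Named numeric vector of length 9 (see `Details`), with attributes
#'   `n_targets_mapped` and `n_effectors_mapped`.
#' @export
extract_features <- function(network, targets, effectors) {
  nodes <- igraph::V(network)$name
  tg <- unique(normalize_protein(targets))
  ef <- unique(normalize_protein(effectors))
  tg_m <- intersect(tg, nodes)
  ef_m <- intersect(ef, nodes)
  dropped <- (length(tg) - length(tg_m)) + (length(ef) - length(ef_m))
  if (dropped > 0) {
    rlang::inform(sprintf("%d protein(s) not in the network dropped", dropped))
  }
  if (length(tg_m) == 0 || length(ef_m) == 0) {
    rlang::abort("no mapped targets or no mapped effectors",
                 class = "ivignet_error_mapping")
  }
  dmat <- igraph::distances(network, v = tg_m, to = ef_m)
  cap <- network_diameter(network) + 1
  dmat[!is.finite(dmat)] <- cap
  min_per_target <- apply(dmat, 1, min)
  pr <- igraph::page_rank(
    network, damping = 0.85,
    personalized = as.numeric(nodes %in% ef_m)
  )$vector
  fv <- c(
    min_hop = min(min_per_target),
    mean_min_hop = mean(min_per_target),
    median_min_hop = stats::median(min_per_target),
    frac_within_2 = mean(min_per_target <= 2),
    jaccard = length(intersect(tg_m, ef_m)) / length(union(tg_m, ef_m)),
    log_n_targets = log1p(length(tg_m)),
    log_n_effectors = log1p(length(ef_m)),
    log_mean_target_degree = log1p(mean(igraph::degree(network, v = tg_m))),
    rw_proximity = sum(pr[match(tg_m, nodes)])
  )
  attr(fv, "n_targets_mapped") <- length(tg_m)
  attr(fv, "n_effectors_mapped") <- length(ef_m)
  fv
}

# diameter over the largest component's finite distances; cached on the graph
# attribute when present so repeated feature extraction stays cheap
network_diameter <- function(network) {
  d <- igraph::graph_attr(network, "ivignet_diameter")
  if (is.null(d)) d <- igraph::diameter(network, directed = FALSE)
  d
}

#' Precompute and cache the network diameter
#'
#' Feature extraction imputes disconnected distances as diameter + 1; caching
#' the diameter on the graph avoids recomputing it for every pair.
#'
#' @param network Protein network.
#' @return The network with a cached diameter attribute.
#' @export
cache_diameter <- function(network) {
  igraph::set_graph_attr(network, "ivignet_diameter",
                         igraph::diameter(network, directed = FALSE))
}

# feature matrix for a tibble of pairs (targets/effectors list-columns)
pair_feature_matrix <- function(pairs, network) {
  network <- cache_diameter(network)
  mats <- purrr::map2(pairs$targets, pairs$effectors,
                      ~ extract_features(network, .x, .y))
  mat <- do.call(rbind, mats)
  rownames(mat) <- NULL
  mat
}
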