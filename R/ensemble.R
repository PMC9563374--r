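# The mechanistic scorer: a stratified bagged ensemble of small multilayer
# perceptrons relating drug-target sets to disease effector sets through
# topological network features. Drugs are stratified by target count; each
# stratum trains its own bag of MLP members on balanced Monte-Carlo
# subsamples, the best-scoring fraction of members is kept, and scores are
# calibrated to empirical p-values on held-out negative pairs.

#' Ensemble configuration
#'
#' @param n_models Total number of MLP members trained (spread evenly over the
#'   strata). The reference architecture uses 1000; the packaged benchmark
#'   default is 40, which preserves the architecture at a fraction of the
#'   cost.
#' @param keep_fraction Fraction of members kept per stratum after ranking by
#'   out-of-subsample accuracy (default 0.75).
#' @param hidden_range Inclusive range of hidden-layer sizes; each member
#'   draws its size uniformly from this range (default 7 to 11).
#' @param strata_boundaries Ordered target-count cut points; a drug with
#'   `n_targets <= boundary[i]` (and above the previous one) falls in stratum
#'   `i`. Default `NULL`: target-count quartiles of the training drugs.
#' @param mc_subsample_fraction Fraction of the minority class drawn (from
#'   each class, giving exact 1:1 balance) into each member's Monte-Carlo
#'   training subsample.
#' @param seed Master seed; member initialization, subsampling and
#'   hidden-size draws all derive from it.
#' @param optimizer `"second_order_least_squares"` (default): members minimize
#'   squared error with a quasi-Newton (BFGS) routine, honoring the
#'   Levenberg-Marquardt-style second-order least-squares fitting of the
#'   reference architecture. `"gradient"`: members are fit on the
#'   cross-entropy loss instead.
#' @param max_epochs Maximum optimizer iterations per member.
#' @param decay Weight decay for member training.
#' @return A validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_models = 40L,
                            keep_fraction = 0.75,
                            hidden_range = c(7L, 11L),
                            strata_boundaries = NULL,
                            mc_subsample_fraction = 0.8,
                            seed = 1L,
                            optimizer = c("second_order_least_squares", "gradient"),
                            max_epochs = 200L,
                            decay = 1e-3) {
  optimizer <- match.arg(optimizer)
  check_range(hidden_range, "hidden_range")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort_config("keep_fraction must lie in (0, 1]")
  }
  if (mc_subsample_fraction <= 0 || mc_subsample_fraction > 1) {
    abort_config("mc_subsample_fraction must lie in (0, 1]")
  }
  if (n_models < 1) abort_config("n_models must be positive")
  if (!is.null(strata_boundaries) && is.unsorted(strata_boundaries, strictly = TRUE)) {
    abort_config("strata_boundaries must be strictly increasing")
  }
  structure(list(
    n_models = as.integer(n_models), keep_fraction = keep_fraction,
    hidden_range = as.integer(hidden_range),
    strata_boundaries = strata_boundaries,
    mc_subsample_fraction = mc_subsample_fraction,
    seed = as.integer(seed), optimizer = optimizer,
    max_epochs = as.integer(max_epochs), decay = decay
  ), class = "ensemble_config")
}

# stratum index for target counts given boundaries (upper-inclusive cuts)
assign_stratum <- function(n_targets, boundaries) {
  findInterval(n_targets, c(boundaries, Inf), left.open = TRUE) + 1L
}

#' Train the stratified bagged MLP ensemble
#'
#' Pairs are stratified by drug target count. Within each stratum every
#' member: (1) draws a balanced Monte-Carlo subsample (the same number of
#' related and unrelated pairs, `mc_subsample_fraction` of the minority class
#' size); (2) trains a one-hidden-layer perceptron with a single
#' relation/no-relation output node and a hidden size drawn uniformly from
#' `hidden_range`; (3) is scored on its out-of-subsample pairs within the
#' stratum. The best `keep_fraction` of members per stratum (by validation
#' accuracy, ties broken by member index) form the final model. Training is
#' fully deterministic for a fixed config seed.
#'
#' @param pairs Labeled pair tibble (see [generate_training_pairs()]): columns
#'   `pair_id`, `targets`, `effectors`, `label`.
#' @param network Protein network.
#' @param config An [ensemble_config()].
#' @return An object of class `ivig_ensemble`.
#' @export
train_ensemble <- function(pairs, network, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  if (!all(c("targets", "effectors", "label") %in% names(pairs))) {
    abort_validation("pairs must have targets, effectors and label columns")
  }
  if (!"pair_id" %in% names(pairs)) pairs$pair_id <- seq_len(nrow(pairs))
  feats <- pair_feature_matrix(pairs, network)
  y <- as.integer(pairs$label == "related")
  if (length(unique(y)) < 2) abort_validation("training pairs must contain both classes")

  center <- colMeans(feats)
  scale <- apply(feats, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  x <- sweep(sweep(feats, 2, center), 2, scale, "/")

  n_targets <- purrr::map_int(pairs$targets, length)
  boundaries <- config$strata_boundaries
  if (is.null(boundaries)) {
    boundaries <- sort(unique(stats::quantile(n_targets, c(0.25, 0.5, 0.75),
                                              type = 1, names = FALSE)))
    boundaries <- boundaries[boundaries < max(n_targets)]
  }
  stratum <- assign_stratum(n_targets, boundaries)

  # merge single-class strata into their lower neighbor
  repeat {
    bad <- NULL
    for (s in sort(unique(stratum))) {
      if (length(unique(y[stratum == s])) < 2) { bad <- s; break }
    }
    if (is.null(bad)) break
    if (length(unique(stratum)) == 1) {
      abort_validation("a single stratum remains and it is single-class")
    }
    rlang::warn(sprintf("stratum %d is single-class: merging into its neighbor", bad))
    others <- setdiff(sort(unique(stratum)), bad)
    neighbor <- others[which.min(abs(others - bad))]
    stratum[stratum == bad] <- neighbor
  }
  strata_ids <- sort(unique(stratum))

  # spread members evenly over strata, remainder to the earliest strata
  base <- config$n_models %/% length(strata_ids)
  extra <- config$n_models %% length(strata_ids)
  members_per_stratum <- rlang::set_names(
    base + as.integer(seq_along(strata_ids) <= extra), strata_ids)

  strata <- purrr::map(strata_ids, function(s) {
    idx <- which(stratum == s)
    n_members <- members_per_stratum[[as.character(s)]]
    fits <- purrr::map(seq_len(n_members), function(m) {
      withr::with_seed(sub_seed(config$seed, sprintf("member_%d_%d", s, m)), {
        pos <- idx[y[idx] == 1]
        neg <- idx[y[idx] == 0]
        n_take <- max(2L, round(config$mc_subsample_fraction * min(length(pos), length(neg))))
        n_take <- min(n_take, length(pos), length(neg))
        sub <- c(sample(pos, n_take), sample(neg, n_take))
        hidden <- sample(seq(config$hidden_range[1], config$hidden_range[2]), 1)
        fit <- nnet::nnet(x[sub, , drop = FALSE], y[sub], size = hidden,
                          entropy = (config$optimizer == "gradient"),
                          maxit = config$max_epochs, decay = config$decay,
                          trace = FALSE)
        oos <- setdiff(idx, sub)
        val_idx <- if (length(oos) > 0) oos else sub
        pred <- as.numeric(stats::predict(fit, x[val_idx, , drop = FALSE]))
        acc <- mean((pred >= 0.5) == (y[val_idx] == 1))
        list(fit = fit, hidden = hidden, subsample = pairs$pair_id[sub],
             val_accuracy = acc)
      })
    })
    meta <- tibble::tibble(
      member = seq_len(n_members),
      hidden = purrr::map_int(fits, "hidden"),
      val_accuracy = purrr::map_dbl(fits, "val_accuracy")
    )
    n_keep <- ceiling(config$keep_fraction * n_members)
    keep_order <- order(-meta$val_accuracy, meta$member)
    meta$kept <- meta$member %in% keep_order[seq_len(n_keep)]
    list(stratum = s, fits = fits, meta = meta,
         n_targets_range = range(n_targets[idx]))
  })
  names(strata) <- as.character(strata_ids)

  structure(list(
    strata = strata,
    boundaries = boundaries,
    standardization = list(center = center, scale = scale),
    feature_names = FEATURE_NAMES,
    config = config,
    trained_pair_ids = pairs$pair_id,
    calibration = NULL
  ), class = "ivig_ensemble")
}

#' @export
print.ivig_ensemble <- function(x, ...) {
  kept <- sum(purrr::map_int(x$strata, ~ sum(.x$meta$kept)))
  total <- sum(purrr::map_int(x$strata, ~ nrow(.x$meta)))
  cat(sprintf("<ivig_ensemble> %d strata, %d/%d members kept, %s\n",
              length(x$strata), kept, total,
              if (is.null(x$calibration)) "uncalibrated" else "calibrated"))
  invisible(x)
}

# raw ensemble output in [0, 100] for one standardized feature vector,
# using only the kept members of the selected stratum
score_feature_vector <- function(ensemble, fv, n_targets) {
  x <- (fv - ensemble$standardization$center) / ensemble$standardization$scale
  s <- assign_stratum(n_targets, ensemble$boundaries)
  avail <- as.integer(names(ensemble$strata))
  if (!s %in% avail) {
    nearest <- avail[which.min(abs(avail - s))]
    rlang::warn(sprintf("target count %d outside trained strata: routed to stratum %d",
                        n_targets, nearest))
    s <- nearest
  }
  st <- ensemble$strata[[as.character(s)]]
  kept <- which(st$meta$kept)
  preds <- purrr::map_dbl(kept, function(m) {
    as.numeric(stats::predict(st$fits[[m]]$fit, matrix(x, nrow = 1)))
  })
  list(score = 100 * mean(pmin(pmax(preds, 0), 1)), stratum = s)
}

#' Calibrate ensemble scores to empirical p-values
#'
#' Associates every score with the empirical false-positive rate among known
#' unrelated calibration pairs: `p(s)` is the fraction of negative calibration
#' pairs scoring at least `s`. The mapping is a non-increasing step function
#' by construction. Calibration pairs should be disjoint from the training
#' pairs; overlap triggers a warning.
#'
#' @param ensemble A trained [train_ensemble()] model.
#' @param pairs Labeled calibration pairs (must include unrelated pairs).
#' @param network Protein network.
#' @return The ensemble with a filled `calibration` component.
#' @export
calibrate <- function(ensemble, pairs, network) {
  stopifnot(inherits(ensemble, "ivig_ensemble"))
  if (!"pair_id" %in% names(pairs)) pairs$pair_id <- seq_len(nrow(pairs))
  overlap <- intersect(pairs$pair_id, ensemble$trained_pair_ids)
  if (length(overlap) > 0) {
    rlang::warn(sprintf("%d calibration pair(s) overlap the training set", length(overlap)))
  }
  neg <- pairs[pairs$label == "unrelated", ]
  if (nrow(neg) == 0) {
    rlang::abort("no unrelated calibration pairs", class = "ivignet_error_calibration")
  }
  feats <- pair_feature_matrix(neg, network)
  n_targets <- purrr::map_int(neg$targets, length)
  scores <- purrr::map_dbl(seq_len(nrow(neg)), function(i) {
    score_feature_vector(ensemble, feats[i, ], n_targets[i])$score
  })
  ensemble$calibration <- list(negative_scores = sort(scores))
  ensemble
}

# empirical FPR lookup: fraction of calibration negatives scoring >= s
calibrated_p <- function(ensemble, score) {
  if (is.null(ensemble$calibration)) return(rep(NA_real_, length(score)))
  neg <- ensemble$calibration$negative_scores
  purrr::map_dbl(score, ~ mean(neg >= .x))
}

#' Map scores and p-values to relationship categories
#'
#' Categories follow the published convention: `strong` for score > 78 and
#' p < 0.05; `medium_strong` for score > 71 and p < 0.1; `medium` for
#' score > 38 and p < 0.25; otherwise `low` (a score of exactly 38 is `low`).
#'
#' @param score Numeric scores in \[0, 100\].
#' @param p_value Calibrated p-values.
#' @param score_cutoffs Strictly-exceeded score boundaries for strong,
#'   medium-strong and medium (default `c(78, 71, 38)`).
#' @param p_cutoffs Strict p-value bounds paired with `score_cutoffs`
#'   (default `c(0.05, 0.1, 0.25)`).
#' @return Factor with levels `strong`, `medium_strong`, `medium`, `low`.
#' @export
score_category <- function(score, p_value,
                           score_cutoffs = c(78, 71, 38),
                           p_cutoffs = c(0.05, 0.1, 0.25)) {
  out <- dplyr::case_when(
    score > score_cutoffs[1] & p_value < p_cutoffs[1] ~ "strong",
    score > score_cutoffs[2] & p_value < p_cutoffs[2] ~ "medium_strong",
    score > score_cutoffs[3] & p_value < p_cutoffs[3] ~ "medium",
    .default = "low"
  )
  factor(out, levels = c("strong", "medium_strong", "medium", "low"))
}

#' Glyphs for relationship categories
#'
#' `+++` strong, `++` medium-strong, `+` medium, `-` low, matching the
#' published display convention.
#'
#' @param category Factor from [score_category()].
#' @return Character vector of glyphs.
#' @export
category_glyph <- function(category) {
  unname(c(strong = "+++", medium_strong = "++", medium = "+", low = "-")[
    as.character(category)])
}

#' Score one target set against one effector set
#'
#' @param ensemble A trained, preferably calibrated, ensemble.
#' @param network Protein network.
#' @param targets Character vector of drug-target identifiers.
#' @param effectors Character vector of disease-effector identifiers.
#' @return One-row tibble with `score`, `p_value`, `category`, `glyph`,
#'   `stratum`, `n_targets_mapped`.
#' @export
score_relationship <- function(ensemble, network, targets, effectors) {
  stopifnot(inherits(ensemble, "ivig_ensemble"))
  if (length(targets) == 0) abort_validation("targets must be non-empty")
  network <- cache_diameter(network)
  fv <- extract_features(network, targets, effectors)
  res <- score_feature_vector(ensemble, fv, attr(fv, "n_targets_mapped"))
  p <- calibrated_p(ensemble, res$score)
  cat_ <- score_category(res$score, p)
  tibble::tibble(
    score = res$score, p_value = p, category = cat_,
    glyph = category_glyph(cat_), stratum = res$stratum,
    n_targets_mapped = attr(fv, "n_targets_mapped")
  )
}

#' Predict relationship scores for a table of pairs
#'
#' @param object A trained `ivig_ensemble`.
#' @param pairs Pair tibble with `targets` and `effectors` list-columns.
#' @param network Protein network.
#' @param ... Unused.
#' @return `pairs` with `score`, `p_value`, `category` and `stratum` columns
#'   appended.
#' @export
predict.ivig_ensemble <- function(object, pairs, network, ...) {
  feats <- pair_feature_matrix(pairs, network)
  n_targets <- purrr::map_int(pairs$targets, length)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    score_feature_vector(object, feats[i, ], n_targets[i])
  })
  pairs$score <- purrr::map_dbl(res, "score")
  pairs$stratum <- purrr::map_int(res, ~ as.integer(.x$stratum))
  pairs$p_value <- calibrated_p(object, pairs$score)
  pairs$category <- score_category(pairs$score, pairs$p_value)
  pairs
}

#' Evaluate a trained ensemble on held-out pairs
#'
#' Pairs whose drugs have any target missing from the network are excluded
#' (with a message), mirroring the convention that performance is reported on
#' drugs fully covered by the network. Accuracy uses a score threshold of 50
#' (score >= 50 predicts related); AUC is the Mann-Whitney rank statistic.
#'
#' @param ensemble A trained ensemble.
#' @param pairs Labeled held-out pairs.
#' @param network Protein network.
#' @return An object of class `ivig_evaluation`: list with `accuracy`, `auc`,
#'   `per_stratum` (tibble), `n_eval_pairs`, `scored` (scored pair tibble).
#' @export
evaluate_ensemble <- function(ensemble, pairs, network) {
  nodes <- igraph::V(network)$name
  covered <- purrr::map_lgl(pairs$targets, ~ all(.x %in% nodes))
  if (!all(covered)) {
    rlang::inform(sprintf("excluding %d pair(s) with unmapped targets", sum(!covered)))
  }
  eligible <- pairs[covered, ]
  if (nrow(eligible) == 0) {
    rlang::abort("no eligible evaluation pairs", class = "ivignet_error_evaluation")
  }
  scored <- predict(ensemble, eligible, network)
  truth <- scored$label == "related"
  pred <- scored$score >= 50
  acc <- mean(pred == truth)
  auc <- rank_auc(scored$score, truth)
  per_stratum <- scored |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean((.data$score >= 50) == (.data$label == "related")),
      .groups = "drop"
    )
  structure(list(accuracy = acc, auc = auc, per_stratum = per_stratum,
                 n_eval_pairs = nrow(eligible), scored = scored),
            class = "ivig_evaluation")
}

# Mann-Whitney AUC from ranks; NA when a class is absent
rank_auc <- function(score, truth) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.ivig_evaluation <- function(x, ...) {
  cat(sprintf("<ivig_evaluation> n = %d, accuracy = %.3f, AUC = %.3f\n",
              x$n_eval_pairs, x$accuracy, x$auc))
  invisible(x)
}

#' @rdname evaluate_ensemble
#' @param x An `ivig_evaluation`.
#' @param ... Unused.
#' @method glance ivig_evaluation
#' @export
glance.ivig_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc, n_eval_pairs = x$n_eval_pairs)
}

#' @rdname train_ensemble
#' @param x An `ivig_ensemble`.
#' @param ... Unused.
#' @method tidy ivig_ensemble
#' @export
tidy.ivig_ensemble <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$strata, function(st, s) {
    dplyr::mutate(st$meta, stratum = as.integer(s), .before = 1)
  }))
}

#' @rdname train_ensemble
#' @method glance ivig_ensemble
#' @export
glance.ivig_ensemble <- function(x, ...) {
  meta <- tidy(x)
  tibble::tibble(
    n_strata = length(x$strata),
    n_members = nrow(meta),
    n_kept = sum(meta$kept),
    mean_val_accuracy = mean(meta$val_accuracy[meta$kept]),
    calibrated = !is.null(x$calibration)
  )
}

#' Score a functional target group as a pseudo-drug
#'
#' Treats the subset of a drug's targets annotated with `group` as a
#' pseudo-drug and scores it against a disease's effector set. Scoring an
#' individual target is the singleton case.
#'
#' @param ensemble A trained ensemble.
#' @param network Protein network.
#' @param group Functional group label (matched against the profile's
#'   `functional_group`).
#' @param drug One-row drug profile from [as_drug_profile()].
#' @param effectors Character vector of disease effector identifiers.
#' @return One-row tibble as [score_relationship()], plus `group` and
#'   `n_targets_in_group`.
#' @export
score_functional_group <- function(ensemble, network, group, drug, effectors) {
  stopifnot(is.data.frame(drug), nrow(drug) == 1)
  tt <- drug$targets[[1]]
  sel <- tt$functional_group == group
  if (!any(sel, na.rm = TRUE)) {
    abort_validation(sprintf("no targets in functional group '%s'", group))
  }
  sub <- tt$protein[which(sel)]
  out <- score_relationship(ensemble, network, sub, effectors)
  dplyr::mutate(out, group = group, n_targets_in_group = length(sub), .before = 1)
}

#' Score grid of targets (or functional groups) against diseases
#'
#' Reproduces the published grid layout: one row per target (or functional
#' group) and disease, with the ensemble score, calibrated p-value, category
#' and display glyph.
#'
#' @param ensemble A trained, calibrated ensemble.
#' @param network Protein network.
#' @param targets Target table (as [ivig_direct_targets()]).
#' @param diseases Disease tibble with non-empty effector sets.
#' @param level `"target"` (singletons) or `"group"` (pseudo-drugs per
#'   functional group).
#' @return Long tibble with `unit`, `disease_id`, `score`, `p_value`,
#'   `category`, `glyph`.
#' @export
score_grid <- function(ensemble, network, targets, diseases,
                       level = c("target", "group")) {
  level <- match.arg(level)
  network <- cache_diameter(network)
  keep <- purrr::map_int(diseases$effectors, length) > 0
  diseases <- diseases[keep, ]
  if (nrow(diseases) == 0) abort_validation("no diseases with effector sets")
  profile <- as_drug_profile(targets)
  tt <- profile$targets[[1]]
  units <- if (level == "target") {
    rlang::set_names(as.list(tt$protein), tt$protein)
  } else {
    split(tt$protein, tt$functional_group)
  }
  nodes <- igraph::V(network)$name
  grid <- tidyr::expand_grid(unit = names(units), disease_id = diseases$disease_id)
  rows <- purrr::map2(grid$unit, grid$disease_id, function(u, d) {
    tg <- units[[u]]
    if (!any(tg %in% nodes)) {
      return(tibble::tibble(score = NA_real_, p_value = NA_real_,
                            category = factor(NA, levels = levels(score_category(0, 1))),
                            glyph = NA_character_, stratum = NA_integer_,
                            n_targets_mapped = 0L))
    }
    eff <- diseases$effectors[[match(d, diseases$disease_id)]]
    score_relationship(ensemble, network, tg, eff)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}
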