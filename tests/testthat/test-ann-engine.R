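# Shared small training setup, built once per test file run.
ann_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 1, n_pairs = 200)
      net <- generate_network(cfg)
      panel <- generate_disease_panel(cfg, net)
      pairs <- generate_training_pairs(cfg, net, panel)
      train <- pairs[1:120, ]; cal <- pairs[121:160, ]; test <- pairs[161:200, ]
      ecfg <- ensemble_config(n_models = 8, seed = 1)
      model <- calibrate(train_ensemble(train, net, ecfg), cal, net)
      cache <<- list(cfg = cfg, net = net, panel = panel, pairs = pairs,
                     train = train, cal = cal, test = test,
                     ecfg = ecfg, model = model)
    }
    cache
  }
})

test_that("feature extraction matches hand-derived topology", {
  g <- path_graph(3)  # a-b-c
  fv <- extract_features(g, targets = "A", effectors = "C")
  expect_equal(unname(fv["min_hop"]), 2)
  expect_equal(unname(fv["jaccard"]), 0)
  expect_length(fv, 9)

  ident <- extract_features(g, targets = c("A", "B"), effectors = c("A", "B"))
  expect_equal(unname(ident["min_hop"]), 0)
  expect_equal(unname(ident["jaccard"]), 1)
  expect_equal(unname(ident["frac_within_2"]), 1)
})

test_that("disconnected pairs get diameter + 1 imputation and all features stay finite", {
  g <- two_triangles()  # diameter 1 within components
  fv <- extract_features(g, targets = "A", effectors = "X")
  expect_equal(unname(fv["min_hop"]), igraph::diameter(g) + 1)
  expect_true(all(is.finite(fv)))
})

test_that("unmapped identifiers are dropped; fully unmapped errors", {
  g <- path_graph(3)
  expect_message(fv <- extract_features(g, c("A", "NOPE"), "C"), "dropped")
  expect_equal(attr(fv, "n_targets_mapped"), 1)
  expect_error(suppressMessages(extract_features(g, "NOPE", "C")),
               class = "ivignet_error_mapping")
})

test_that("member bookkeeping: kept count is ceil(keep_fraction x members per stratum)", {
  s <- ann_setup()
  meta <- tidy(s$model)
  per_stratum <- dplyr::count(meta, .data$stratum, wt = as.integer(.data$kept))
  trained <- dplyr::count(meta, .data$stratum)
  expect_equal(per_stratum$n, ceiling(0.75 * trained$n))
  expect_equal(sum(trained$n), 8)
  expect_true(all(meta$hidden >= 7 & meta$hidden <= 11))
  # ties broken by member index: kept members are the top of a stable ordering
  for (st in split(meta, meta$stratum)) {
    ord <- st[order(-st$val_accuracy, st$member), ]
    expect_true(all(ord$kept[seq_len(sum(st$kept))]))
  }
})

test_that("training and scoring are deterministic for a fixed seed", {
  s <- ann_setup()
  model2 <- calibrate(train_ensemble(s$train, s$net, s$ecfg), s$cal, s$net)
  p1 <- predict(s$model, s$test[1:10, ], s$net)
  p2 <- predict(model2, s$test[1:10, ], s$net)
  expect_identical(p1$score, p2$score)
  expect_identical(s$model$calibration$negative_scores,
                   model2$calibration$negative_scores)
})

test_that("scores are bounded and calibration is a non-increasing step function", {
  s <- ann_setup()
  scored <- predict(s$model, s$test, s$net)
  expect_true(all(scored$score >= 0 & scored$score <= 100))
  grid <- seq(0, 100, by = 5)
  p <- ivignet:::calibrated_p(s$model, grid)
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(p[1], 1)   # every negative scores >= 0
})

test_that("calibrated p is the empirical negative exceedance fraction", {
  fake <- structure(list(calibration = list(negative_scores = c(10, 50, 90))),
                    class = "ivig_ensemble")
  expect_equal(ivignet:::calibrated_p(fake, 60), 1 / 3)
  expect_equal(ivignet:::calibrated_p(fake, 0), 1)
  expect_equal(ivignet:::calibrated_p(fake, 95), 0)
  uncal <- structure(list(calibration = NULL), class = "ivig_ensemble")
  expect_true(is.na(ivignet:::calibrated_p(uncal, 50)))
})

test_that("calibration requires negatives and flags training overlap", {
  s <- ann_setup()
  pos_only <- s$cal[s$cal$label == "related", ]
  expect_error(calibrate(s$model, pos_only, s$net),
               class = "ivignet_error_calibration")
  mixed <- dplyr::bind_rows(utils::head(s$train[s$train$label == "related", ], 5),
                            utils::head(s$train[s$train$label == "unrelated", ], 5))
  expect_warning(calibrate(s$model, mixed, s$net), "overlap")
})

test_that("category mapping honors the published score/p boundaries exactly", {
  expect_equal(as.character(score_category(86, 0.03)), "strong")
  expect_equal(as.character(score_category(72, 0.08)), "medium_strong")
  expect_equal(as.character(score_category(50, 0.2)), "medium")
  expect_equal(as.character(score_category(38, 0.01)), "low")     # <= 38 edge
  expect_equal(as.character(score_category(38.0001, 0.2)), "medium")
  expect_equal(as.character(score_category(79, 0.07)), "medium_strong")
  expect_equal(as.character(score_category(90, 0.5)), "low")
  expect_equal(category_glyph(score_category(c(86, 72, 50, 10), c(0.01, 0.08, 0.2, 0.9))),
               c("+++", "++", "+", "-"))
})

test_that("rank AUC behaves as the Mann-Whitney statistic", {
  expect_equal(ivignet:::rank_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(ivignet:::rank_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(ivignet:::rank_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # cross-check against an independent ROC implementation
  withr::with_seed(7, {
    score <- stats::rnorm(40)
    truth <- stats::runif(40) > 0.4
    expect_equal(ivignet:::rank_auc(score, truth),
                 as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                                direction = "<"))))
  })
  # permutation null centered at 0.5
  withr::with_seed(33, {
    score <- stats::rnorm(60)
    truth <- rep(c(TRUE, FALSE), 30)
    aucs <- purrr::map_dbl(1:100, ~ ivignet:::rank_auc(score, sample(truth)))
    expect_gt(mean(aucs), 0.45)
    expect_lt(mean(aucs), 0.55)
  })
})

test_that("evaluation excludes uncovered drugs and applies the >= 50 tie rule", {
  s <- ann_setup()
  broken <- s$test
  broken$targets[[1]] <- c(broken$targets[[1]], "NOT_A_NODE")
  expect_message(ev <- evaluate_ensemble(s$model, broken, s$net), "excluding 1")
  expect_equal(ev$n_eval_pairs, nrow(s$test) - 1)
  expect_s3_class(glance(ev), "tbl_df")

  # all-tie scores predict 'related', so accuracy is the related fraction
  scored <- ev$scored
  const_pred <- rep(TRUE, nrow(scored))
  expect_equal(mean(const_pred == (scored$label == "related")),
               mean(scored$label == "related"))
})

test_that("prediction uses only kept members of the drug's own stratum", {
  s <- ann_setup()
  one <- s$test[5, ]
  res <- score_relationship(s$model, s$net, one$targets[[1]], one$effectors[[1]])
  st <- s$model$strata[[as.character(res$stratum)]]
  x <- (ivignet:::pair_feature_matrix(one, s$net)[1, ] -
        s$model$standardization$center) / s$model$standardization$scale
  manual <- purrr::map_dbl(which(st$meta$kept), function(m) {
    as.numeric(stats::predict(st$fits[[m]]$fit, matrix(x, nrow = 1)))
  })
  expect_equal(res$score, 100 * mean(pmin(pmax(manual, 0), 1)))
})

test_that("functional-group scoring reduces to predict on the group subset", {
  s <- ann_setup()
  nodes <- igraph::V(s$net)$name
  targets <- tibble::tibble(
    gene = nodes[1:4],
    functional_group = c("Complement system", "Complement system",
                         "B-cell related", "B-cell related"))
  drug <- as_drug_profile(targets, "TESTDRUG")
  eff <- s$panel$effectors[[1]]
  grp <- score_functional_group(s$model, s$net, "Complement system", drug, eff)
  direct <- score_relationship(s$model, s$net, nodes[1:2], eff)
  expect_equal(grp$score, direct$score)
  expect_equal(grp$n_targets_in_group, 2)

  single <- as_drug_profile(tibble::tibble(gene = nodes[1], functional_group = "X"))
  one <- score_functional_group(s$model, s$net, "X", single, eff)
  expect_equal(one$score, score_relationship(s$model, s$net, nodes[1], eff)$score)

  expect_error(score_functional_group(s$model, s$net, "Missing", drug, eff),
               class = "ivignet_error_validation")
})

test_that("moving a single target toward the effectors never hurts the score trend", {
  s <- ann_setup()
  eff <- s$panel$effectors[[3]]
  # walk from a far node toward the effector set along a shortest path
  d_all <- igraph::distances(s$net, to = eff)
  min_d <- apply(d_all, 1, min)
  far <- names(which.max(min_d))
  nearest_eff <- eff[which.min(igraph::distances(s$net, v = far, to = eff))]
  path <- igraph::shortest_paths(s$net, from = far, to = nearest_eff)$vpath[[1]]$name
  scores <- purrr::map_dbl(path, function(v) {
    score_relationship(s$model, s$net, v, eff)$score
  })
  hops <- min_d[path]
  rho <- stats::cor(hops, scores, method = "spearman")
  expect_lte(rho, 0)
})

test_that("score grid covers units x diseases with glyphs", {
  s <- ann_setup()
  nodes <- igraph::V(s$net)$name
  targets <- tibble::tibble(gene = nodes[1:3],
                            functional_group = c("G1", "G1", "G2"))
  grid <- score_grid(s$model, s$net, targets, s$panel[1:4, ], level = "target")
  expect_equal(nrow(grid), 3 * 4)
  expect_true(all(grid$glyph %in% c("+++", "++", "+", "-")))
  ggrid <- score_grid(s$model, s$net, targets, s$panel[1:4, ], level = "group")
  expect_equal(nrow(ggrid), 2 * 4)
})

test_that("degenerate training inputs raise the documented errors", {
  s <- ann_setup()
  one_class <- s$train[s$train$label == "related", ]
  expect_error(train_ensemble(one_class, s$net, s$ecfg),
               class = "ivignet_error_validation")
  expect_error(ensemble_config(keep_fraction = 0), class = "ivignet_error_config")
  expect_error(ensemble_config(strata_boundaries = c(5, 3)),
               class = "ivignet_error_config")
})
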