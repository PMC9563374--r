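test_that("network generator is deterministic and seed-sensitive", {
  cfg <- synthetic_config(seed = 1, n_nodes = 300)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_equal(igraph::vcount(g1), 300)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_equal(igraph::components(g1)$no, 1)

  g3 <- generate_network(synthetic_config(seed = 2, n_nodes = 300))
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
})

test_that("infeasible generator parameters raise configuration errors", {
  expect_error(synthetic_config(n_nodes = 3, attachment_m = 5),
               class = "ivignet_error_config")
  expect_error(synthetic_config(positive_fraction = 1),
               class = "ivignet_error_config")
  expect_error(synthetic_config(effector_count_range = c(10, 500), n_nodes = 300),
               class = "ivignet_error_config")
})

test_that("disease panel respects cluster counts and guaranteed process groups", {
  cfg <- synthetic_config(seed = 3)
  net <- generate_network(cfg)
  panel <- generate_disease_panel(cfg, net)
  expect_equal(as.vector(table(panel$cluster)), c(7, 6, 9, 4))
  groups <- purrr::map(panel$processes, ~ unique(.x$group))
  expect_true(all(purrr::map_lgl(groups[panel$cluster == "DB"],
                                 ~ all(c(1, 4) %in% .x))))
  expect_true(all(purrr::map_lgl(groups[panel$cluster %in% c("MPB", "UPB")],
                                 ~ 3 %in% .x)))
  expect_identical(panel, generate_disease_panel(cfg, net))
  # effector invariants
  expect_equal(purrr::map_int(panel$effectors, length), panel$effector_count)
})

test_that("empty panel request warns and returns an empty table", {
  cfg <- synthetic_config(seed = 1,
                          n_diseases_per_cluster = c(DB = 0L, PB = 0L, MPB = 0L, UPB = 0L))
  net <- generate_network(cfg)
  expect_warning(panel <- generate_disease_panel(cfg, net), "empty panel")
  expect_equal(nrow(panel), 0)
})

test_that("training pairs are balanced, reproducible and distance-separated", {
  cfg <- synthetic_config(seed = 7, n_pairs = 200)
  net <- generate_network(cfg)
  panel <- generate_disease_panel(cfg, net)
  pairs <- generate_training_pairs(cfg, net, panel)
  expect_equal(nrow(pairs), 200)
  expect_equal(sum(pairs$label == "related"), 100)
  expect_identical(pairs, generate_training_pairs(cfg, net, panel))

  min_dist <- purrr::map2_dbl(pairs$targets, pairs$effectors, function(tg, ef) {
    min(igraph::distances(net, v = tg, to = ef))
  })
  expect_true(all(min_dist[pairs$label == "related"] <= cfg$proximity_radius))
  expect_true(all(min_dist[pairs$label == "unrelated"] >= cfg$proximity_radius + 2))
})

test_that("positive pairs sit closer to effectors than negatives across seeds", {
  med <- purrr::map(1:20, function(s) {
    cfg <- synthetic_config(seed = s, n_pairs = 40)
    net <- generate_network(cfg)
    panel <- generate_disease_panel(cfg, net)
    pairs <- generate_training_pairs(cfg, net, panel)
    d <- purrr::map2_dbl(pairs$targets, pairs$effectors, function(tg, ef) {
      min(igraph::distances(net, v = tg, to = ef))
    })
    c(pos = stats::median(d[pairs$label == "related"]),
      neg = stats::median(d[pairs$label == "unrelated"]))
  })
  med <- do.call(rbind, med)
  expect_true(all(med[, "pos"] < med[, "neg"]))
})

test_that("pathway generator plants signal and serializes deterministically", {
  cfg <- synthetic_config(seed = 11, n_pathways = 50)
  net <- generate_network(cfg)
  panel <- generate_disease_panel(cfg, net)
  db <- generate_pathway_db(cfg, net, panel)
  expect_length(db$pathways, 50)
  sizes <- lengths(db$pathways)
  expect_true(all(sizes >= cfg$pathway_size_range[1] &
                  sizes <= cfg$pathway_size_range[2]))
  expect_equal(db$universe, sort(igraph::V(net)$name))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gene_sets(db, f1)
  write_gene_sets(generate_pathway_db(cfg, net, panel), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted pathways overlap disease effectors more than decoys", {
  overlaps <- purrr::map(1:20, function(s) {
    cfg <- synthetic_config(seed = s, n_pathways = 20)
    net <- generate_network(cfg)
    panel <- generate_disease_panel(cfg, net)
    db <- generate_pathway_db(cfg, net, panel)
    all_eff <- unique(unlist(panel$effectors))
    ov <- purrr::map_dbl(db$pathways, ~ length(intersect(.x, all_eff)) / length(.x))
    c(planted = mean(ov[grepl("^PLANTED", names(ov))]),
      decoy = mean(ov[grepl("^DECOY", names(ov))]))
  })
  overlaps <- do.call(rbind, overlaps)
  expect_gt(mean(overlaps[, "planted"]), mean(overlaps[, "decoy"]))
})
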