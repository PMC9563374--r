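make_db <- function(pathways, universe = NULL) {
  f <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  lines <- purrr::imap_chr(pathways, ~ paste(c(.y, "d", .x), collapse = "\t"))
  writeLines(lines, f)
  read_gene_sets(f, universe = universe)
}

test_that("hypergeometric p matches exhaustive enumeration on spot checks", {
  # exhaustive agreement over all N <= 15 lives in the acceptance suite;
  # spot-check the enrichment route against the enumeration oracle here
  for (case in list(c(8, 3, 4, 2), c(10, 5, 5, 3), c(12, 6, 4, 0))) {
    N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment reproduces hand-computable tail cases", {
  universe <- sprintf("G%02d", 1:10)
  db <- make_db(list(PW = universe[1:5]), universe = universe)
  # query = pathway: N=10, K=5, n=5, k=5 -> 1/choose(10,5) = 1/252
  res <- hypergeometric_enrich(universe[1:5], db)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(enum_hyper_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)

  # disjoint query with K + n <= N: k=0 -> p = 1
  res0 <- hypergeometric_enrich(universe[6:10], db)
  expect_equal(res0$k, 0)
  expect_equal(res0$p_value, 1)

  # pathway == query == universe -> certain event
  db_all <- make_db(list(PW = universe))
  res_all <- hypergeometric_enrich(universe, db_all)
  expect_equal(res_all$p_value, 1)
})

test_that("query proteins outside the universe are dropped, empty query errors", {
  db <- make_db(list(PW = c("A", "B", "C")))
  expect_message(res <- hypergeometric_enrich(c("A", "ZZZ"), db), "dropped")
  expect_equal(res$n, 1)
  expect_error(suppressMessages(hypergeometric_enrich("ZZZ", db)),
               class = "ivignet_error_validation")
})

test_that("growing the universe with irrelevant proteins never increases p", {
  withr::with_seed(13, {
    for (i in 1:20) {
      members <- sample(LETTERS[1:15], 6)
      query <- sample(LETTERS[1:15], 5)
      db1 <- make_db(list(PW = members), universe = LETTERS[1:15])
      db2 <- make_db(list(PW = members), universe = c(LETTERS[1:15], letters))
      p1 <- suppressMessages(hypergeometric_enrich(query, db1))$p_value
      p2 <- suppressMessages(hypergeometric_enrich(query, db2))$p_value
      expect_lte(p2, p1 + 1e-12)
    }
  })
})

test_that("BH correction equals the hand-evaluated step-up formula", {
  res <- tibble::tibble(pathway_id = paste0("p", 1:4),
                        p_value = c(0.01, 0.02, 0.03, 0.04))
  q <- bh_correct(res)$q_value
  expect_equal(q, c(0.04, 0.04, 0.04, 0.04))

  expect_equal(bh_correct(tibble::tibble(p_value = 0.2))$q_value, 0.2)
  all1 <- bh_correct(tibble::tibble(p_value = rep(1, 5)))
  expect_true(all(all1$q_value == 1))
  expect_false(any(all1$significant))

  withr::with_seed(4, {
    for (i in 1:20) {
      p <- stats::runif(sample(3:30, 1))
      got <- bh_correct(tibble::tibble(p_value = p))
      want <- stepup_bh(sort(p))
      expect_equal(got$q_value, want, tolerance = 1e-12)
      expect_true(all(diff(got$q_value) >= -1e-12))   # monotone along sorted p
      expect_true(all(got$q_value >= got$p_value - 1e-12))
      # order invariance of the significant set
      got2 <- bh_correct(tibble::tibble(p_value = rev(p)))
      expect_setequal(got$p_value[got$significant], got2$p_value[got2$significant])
    }
  })
})

test_that("planted pathways enrich the DB-without-UPB compartment above decoys", {
  rates <- purrr::map(1:10, function(s) {
    cfg <- synthetic_config(seed = s)
    net <- generate_network(cfg)
    panel <- generate_disease_panel(cfg, net)
    db <- generate_pathway_db(cfg, net, panel)
    unions <- cluster_unions(panel)
    vp <- venn_partition(unions$DB, unions$PB, unions$MPB, unions$UPB)
    res <- enrich(vp$db_without_upb, db)
    planted <- grepl("^PLANTED", res$pathway_id)
    c(planted = mean(res$significant[planted]),
      decoy = mean(res$significant[!planted]))
  })
  rates <- do.call(rbind, rates)
  expect_gt(mean(rates[, "planted"]), mean(rates[, "decoy"]))
})

test_that("Hausdorff pathway graph follows the strict-threshold rule", {
  g <- path_graph(3)  # a-b-c
  db <- make_db(list(P = c("A"), Q = c("B"), R = c("A")), universe = c("A", "B", "C"))
  enr <- tibble::tibble(pathway_id = c("P", "Q", "R"))
  pg <- pathway_similarity_graph(enr, db, g, threshold = 1)
  # identical coverage: distance 0 -> edge; adjacent singletons: distance 1 -> no edge
  expect_equal(nrow(pg$edges), 1)
  expect_setequal(unlist(pg$edges[, c("from", "to")]), c("P", "R"))
  d_pq <- pg$all_distances$distance[pg$all_distances$from == "P" &
                                    pg$all_distances$to == "Q"]
  expect_equal(d_pq, 1)
})

test_that("pathways in different components are never connected", {
  g <- two_triangles()
  db <- make_db(list(P = c("A", "B"), Q = c("X", "Y")),
                universe = igraph::V(g)$name)
  enr <- tibble::tibble(pathway_id = c("P", "Q"))
  pg <- pathway_similarity_graph(enr, db, g, threshold = 100)
  expect_equal(nrow(pg$edges), 0)
  expect_equal(max(pg$components$component), 2)
})

test_that("unmapped pathway members are dropped and empty pathways excluded", {
  g <- path_graph(3)
  db <- make_db(list(P = c("A", "ZZ"), Q = c("QQ")), universe = c("A", "B", "C", "ZZ", "QQ"))
  enr <- tibble::tibble(pathway_id = c("P", "Q"))
  expect_warning(
    pg <- suppressMessages(pathway_similarity_graph(enr, db, g, threshold = 1)),
    "no mapped members")
  expect_equal(pg$nodes, "P")
})

test_that("normalized metric rescales hop distances by the diameter", {
  g <- path_graph(5)  # diameter 4
  db <- make_db(list(P = "A", Q = "C"), universe = igraph::V(g)$name)
  enr <- tibble::tibble(pathway_id = c("P", "Q"))
  pg <- pathway_similarity_graph(enr, db, g, threshold = 1, metric = "normalized")
  expect_equal(pg$all_distances$distance, 2 / 4)
  expect_equal(nrow(pg$edges), 1)
})
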