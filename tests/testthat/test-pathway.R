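g <- build_pathway()

test_that("the default graph reaches the published C20 product sets", {
  nmi <- reachable_products(g, chain = 20, class = "nmi")
  expect_equal(nrow(nmi), 4L)
  expect_setequal(nmi$id, c("20:2^Δ5,11^", "20:2^Δ5,13^",
                            "20:3^Δ5,11,14^", "20:4^Δ5,11,14,17^"))
  mi <- reachable_products(g, chain = 20, class = "methylene_interrupted")
  expect_true(all(c("20:2n-6", "20:3n-3", "20:3n-6", "20:4n-3",
                    "20:4n-6", "20:5n-3") %in% mi$shorthand))
})

test_that("edges carry their enzyme provenance", {
  e <- dplyr::filter(g$edges, enzyme == "FadsC2")
  expect_true(fa_to_delta("20:2n-6") %in% e$substrate)
  expect_true(fa_to_delta("20:3n-6") %in% e$product)
  expect_true("20:2^Δ5,11^" %in% g$nodes$id)
})

test_that("C24 products are reachable but DHA is not", {
  expect_true(all(fa_to_delta(c("24:4n-6", "24:5n-3")) %in% g$nodes$id))
  expect_false(fa_to_delta("22:6n-3") %in% g$nodes$id)
})

test_that("ARA and EPA are made by elongation, then Δ8, then Δ5", {
  for (target in c("20:4n-6", "20:5n-3")) {
    r <- routes_to(g, target)
    expect_gt(nrow(r), 0)
    one <- dplyr::filter(r, route == 1)
    expect_equal(nrow(one), 3L)
    expect_equal(one$activity_label, c("C18->C20", "Δ8", "Δ5"))
  }
  # no route to ARA/EPA ever uses a Δ6 edge (that pathway is absent here)
  all_steps <- dplyr::bind_rows(routes_to(g, "20:4n-6"), routes_to(g, "20:5n-3"))
  expect_false(any(all_steps$activity_label == "Δ6"))
})

test_that("the dienoic NMI route runs through iterated MUFA elongation", {
  r <- routes_to(g, "20:2^Δ5,13^")
  one <- dplyr::filter(r, route == 1)
  expect_equal(one$substrate,
               fa_to_delta(c("16:1n-7", "18:1n-7", "20:1n-7")))
  expect_equal(one$enzyme, c("Elovl6-like C", "Elovl6-like C", "FadsA"))
})

test_that("routes to a precursor are empty and unknown targets error", {
  expect_equal(nrow(routes_to(g, "18:2n-6")), 0L)
  expect_error(routes_to(g, "22:6n-3"), class = "pufapath_input_error")
})

test_that("graph is acyclic and respects the chain cap", {
  expect_true(igraph::is_dag(g$graph))
  expect_true(all(g$nodes$chain <= 24))
})

test_that("raising the threshold never adds nodes or edges", {
  prev <- g
  for (thr in c(10, 20, 50, 100)) {
    gt <- build_pathway(threshold = thr)
    expect_true(all(gt$nodes$id %in% prev$nodes$id))
    expect_lte(nrow(gt$edges), nrow(prev$edges))
    prev <- gt
  }
  # at 100% only qualitative edges survive, so no quantified edge remains
  g100 <- build_pathway(threshold = 100)
  expect_true(all(g100$edges$status == "qualitative"))
})

test_that("precursor-only graphs and bad inputs behave", {
  # drop qualitative records too: nothing can qualify at threshold 100
  panels <- dplyr::filter(load_activity_panels(), status != "qualitative")
  g0 <- build_pathway(panels = panels, threshold = 100)
  expect_equal(nrow(g0$edges), 0L)
  expect_setequal(g0$nodes$id, g0$precursors)
  expect_error(build_pathway(precursors = character()),
               class = "pufapath_input_error")
})

test_that("tidiers, exports and the reproduction helper are consistent", {
  expect_equal(nrow(tidy(g)), nrow(g$edges))
  gl <- glance(g)
  expect_equal(gl$n_c20_nmi, 4L)
  expect_equal(gl$n_nodes, nrow(g$nodes))
  dir <- withr::local_tempdir()
  res <- reproduce_pathway_map(dir)
  expect_equal(nrow(res$c20_nmi), 4L)
  expect_true(file.exists(file.path(dir, "edges.csv")))
  edges_back <- readr::read_csv(file.path(dir, "edges.csv"),
                                show_col_types = FALSE)
  expect_equal(nrow(edges_back), nrow(g$edges))
  dot <- pathway_dot(g)
  expect_true(any(grepl("FadsA", dot)))
})
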