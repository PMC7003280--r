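test_that("co-prescription edges carry exact pair counts", {
  db <- db_from_baskets(c(rep(list(c("A", "B")), 10), list(c("C"))))
  g <- cooccurrence_graph(db)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 10L)
  # never co-occurring herbs have no edge; C is isolated
  expect_equal(g$nodes$degree[g$nodes$herb == "C"], 0L)
  # cross-module consistency: weights equal pair_counts exactly
  pc <- pair_counts(db)
  expect_equal(g$edges[c("herb_a", "herb_b", "weight")],
               setNames(pc, c("herb_a", "herb_b", "weight")))
})

test_that("min_weight prunes edges", {
  db <- db_from_baskets(c(rep(list(c("A", "B")), 5), rep(list(c("A", "C")), 2)))
  g <- cooccurrence_graph(db, min_weight = 3)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$herb_b, "B")
})

test_that("a uniform star retains nothing: alpha from the hub is (2/3)^2", {
  # pure star, hub degree 3, uniform weights; leaves are degree 1 so only the
  # hub side tests each edge, at alpha_ij = (1 - 1/3)^2 = 4/9 > 0.05
  g <- cooccurrence_graph(db_from_baskets(c(
    rep(list(c("Hub", "A")), 10), rep(list(c("Hub", "B")), 10),
    rep(list(c("Hub", "C")), 10)
  )))
  bb <- disparity_filter(g, 0.05)
  from_hub <- ifelse(bb$edges$herb_a == "Hub", bb$edges$alpha_a, bb$edges$alpha_b)
  expect_equal(from_hub, rep(4 / 9, 3))
  expect_false(any(bb$edges$retained))
  expect_false(any(bb$edges$degree_one))
})

test_that("a dominant edge is retained and uniform stars retain nothing testable", {
  # node X with normalized weights ~ (0.98, 0.01, 0.01): heavy edge alpha = 0.02^2
  baskets <- c(rep(list(c("X", "Heavy")), 98), list(c("X", "L1")), list(c("X", "L2")),
               rep(list(c("Heavy", "Other")), 50),
               list(c("L1", "L2")))
  bb <- disparity_filter(cooccurrence_graph(db_from_baskets(baskets)), 0.05)
  heavy <- bb$edges[bb$edges$herb_a == "Heavy" & bb$edges$herb_b == "X", ]
  alpha_from_x <- ifelse(heavy$herb_a == "X", heavy$alpha_a, heavy$alpha_b)
  expect_equal(alpha_from_x, (1 - 0.98)^2)
  expect_true(heavy$retained)
})

test_that("isolated dyads are untestable and kept by convention, flagged", {
  db <- db_from_baskets(rep(list(c("A", "B")), 10))
  bb <- disparity_filter(cooccurrence_graph(db), 0.05)
  expect_true(bb$edges$retained)
  expect_true(bb$edges$degree_one)
})

test_that("backbones are nested in alpha", {
  set.seed(41)
  for (rep in 1:5) {
    db <- random_db(n_items = 10, n_trans = 60, p = runif(1, 0.2, 0.6))
    g <- cooccurrence_graph(db)
    key <- function(b) {
      e <- b$edges[b$edges$retained, ]
      paste(e$herb_a, e$herb_b)
    }
    b_tight <- disparity_filter(g, 0.01)
    b_mid <- disparity_filter(g, 0.05)
    b_loose <- disparity_filter(g, 0.5)
    expect_true(all(key(b_tight) %in% key(b_mid)))
    expect_true(all(key(b_mid) %in% key(b_loose)))
  }
})

test_that("uniform-weight nodes retain nothing from their side when (1-1/k)^(k-1) >= alpha", {
  # node U with 4 uniform edges: (3/4)^3 = 0.42 >= 0.05
  baskets <- unlist(lapply(c("A", "B", "C", "D"), function(x)
    rep(list(c("U", x)), 8)), recursive = FALSE)
  extra <- list(c("A", "B"), c("C", "D"), c("A", "C"), c("B", "D"))
  bb <- disparity_filter(cooccurrence_graph(db_from_baskets(c(baskets, extra))), 0.05)
  u_edges <- bb$edges[bb$edges$herb_a == "U" | bb$edges$herb_b == "U", ]
  from_u <- ifelse(u_edges$herb_a == "U", u_edges$alpha_a, u_edges$alpha_b)
  expect_true(all(from_u >= 0.05))
})

test_that("core extraction filters on raw-graph degree and induces retained edges", {
  db <- db_from_baskets(c(
    rep(list(c("A", "B", "C")), 20),
    list(c("A", "D")), list(c("B", "E"))
  ))
  g <- cooccurrence_graph(db)
  bb <- disparity_filter(g, 0.9)
  all_nodes <- core_subgraph(bb, min_degree = 0)
  expect_setequal(all_nodes$nodes$herb, db$items)
  none <- core_subgraph(bb, min_degree = 99)
  expect_equal(nrow(none$nodes), 0)
  core <- core_subgraph(bb, min_degree = 3)
  expect_setequal(core$nodes$herb, c("A", "B"))
  expect_true(all(core$edges$herb_a %in% c("A", "B") &
                    core$edges$herb_b %in% c("A", "B")))
})

test_that("edge-list and graphml exports round-trip through igraph", {
  set.seed(13)
  db <- random_db(6, 30, 0.5)
  g <- cooccurrence_graph(db)
  bb <- disparity_filter(g, 0.2)
  p1 <- tempfile(fileext = ".csv"); write_edge_list(bb, p1)
  expect_equal(nrow(readr::read_csv(p1, show_col_types = FALSE)), nrow(bb$edges))
  p2 <- tempfile(fileext = ".graphml"); write_graphml(bb, p2)
  ig <- igraph::read_graph(p2, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), sum(bb$edges$retained))
})
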