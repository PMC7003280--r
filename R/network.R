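#' Herb co-prescription graph
#'
#' Builds the weighted undirected graph whose nodes are herbs and whose edge
#' weights are co-prescription counts: the number of transactions in which
#' both herbs of a pair appear. Edges below `min_weight` are dropped.
#'
#' @param db A `transaction_db`.
#' @param min_weight Minimum co-prescription count for an edge (default 1).
#' @return A `herb_graph` object: list with `edges` (tibble `herb_a`,
#'   `herb_b`, `weight`) and `nodes` (tibble `herb`, `degree`, `strength`,
#'   `count`), where degree and strength are computed on the retained edges.
#' @export
cooccurrence_graph <- function(db, min_weight = 1) {
  stopifnot(inherits(db, "transaction_db"))
  edges <- pair_counts(db) |>
    filter(.data$count >= min_weight) |>
    dplyr::rename(weight = "count")

  long <- tibble(
    herb = c(edges$herb_a, edges$herb_b),
    w = c(edges$weight, edges$weight)
  )
  stats_tbl <- long |>
    group_by(.data$herb) |>
    summarise(degree = dplyr::n(), strength = sum(.data$w), .groups = "drop")

  counts <- item_counts(db)
  nodes <- counts |>
    dplyr::left_join(stats_tbl, by = "herb") |>
    mutate(
      degree = dplyr::coalesce(.data$degree, 0L),
      strength = dplyr::coalesce(.data$strength, 0L)
    ) |>
    select("herb", "degree", "strength", "count") |>
    arrange(desc(.data$degree), .data$herb)

  structure(list(edges = edges, nodes = nodes), class = "herb_graph")
}

#' @export
print.herb_graph <- function(x, ...) {
  cat("<herb_graph>", nrow(x$nodes), "herbs,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
tidy.herb_graph <- function(x, ...) x$edges

#' @export
glance.herb_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight),
    max_degree = max(c(0L, x$nodes$degree))
  )
}

#' Multiscale backbone of a weighted graph (disparity filter)
#'
#' Scores every edge against a per-node null model in which a node's
#' strength is split uniformly at random among its edges: for node i with
#' degree k_i >= 2 and normalized edge weight p_ij = w_ij / s_i, the
#' probability that a uniformly random split gives that edge at least p_ij
#' is alpha_ij = (1 - p_ij)^(k_i - 1). An edge is retained when it is
#' significant (alpha_ij < alpha) from at least one endpoint of degree >= 2
#' (the OR rule) or, under `rule = "and"`, from every such endpoint. A
#' degree-1 endpoint yields no test, since its whole strength sits on its
#' single edge; an edge both of whose endpoints have degree 1 is therefore
#' untestable and is retained by convention, flagged in the output.
#'
#' @param g A `herb_graph` from [cooccurrence_graph()].
#' @param alpha Per-edge significance level in (0, 1); 0.05 corresponds to a
#'   95 percent confidence level.
#' @param rule `"or"` (default) or `"and"` endpoint retention rule.
#' @return A `herb_backbone`: list with `edges` (tibble `herb_a`, `herb_b`,
#'   `weight`, `alpha_a`, `alpha_b` — the scores from each endpoint —
#'   `alpha_score` = their minimum (`"or"`) or maximum (`"and"`),
#'   `retained`, `degree_one`), the `alpha` used, the retention `rule`, and
#'   the originating graph `graph`.
#' @examples
#' db <- build_exact_fixture(10, c(A = 10, B = 10), list(list("A", "B", 10)))
#' g <- cooccurrence_graph(db)
#' disparity_filter(g, alpha = 0.05)
#' @export
disparity_filter <- function(g, alpha = 0.05, rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(inherits(g, "herb_graph"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_herbminer("alpha must be in (0, 1)", "herbminer_bad_threshold")
  }
  edges <- g$edges
  deg <- setNames(g$nodes$degree, g$nodes$herb)
  str <- setNames(g$nodes$strength, g$nodes$herb)

  score_from <- function(node, w) {
    k <- deg[node]
    p <- w / str[node]
    ifelse(k >= 2, (1 - p)^(k - 1), NA_real_)
  }
  alpha_a <- score_from(edges$herb_a, edges$weight)
  alpha_b <- score_from(edges$herb_b, edges$weight)
  # edges with no testable endpoint (isolated dyads) are kept by convention
  degree_one <- is.na(alpha_a) & is.na(alpha_b)

  sig_a <- !is.na(alpha_a) & alpha_a < alpha
  sig_b <- !is.na(alpha_b) & alpha_b < alpha
  retained <- if (rule == "or") {
    sig_a | sig_b | degree_one
  } else {
    (sig_a | is.na(alpha_a)) & (sig_b | is.na(alpha_b))
  }

  combine <- if (rule == "or") pmin else pmax
  scored <- edges |>
    mutate(
      alpha_a = unname(alpha_a),
      alpha_b = unname(alpha_b),
      alpha_score = combine(.data$alpha_a, .data$alpha_b, na.rm = TRUE),
      retained = retained,
      degree_one = degree_one
    )

  structure(
    list(edges = scored, alpha = alpha, rule = rule, graph = g),
    class = "herb_backbone"
  )
}

#' @export
print.herb_backbone <- function(x, ...) {
  cat("<herb_backbone>", sum(x$edges$retained), "of", nrow(x$edges),
      "edges retained at alpha =", x$alpha, paste0("(", x$rule, " rule)\n"))
  invisible(x)
}

#' @export
tidy.herb_backbone <- function(x, ...) x$edges

#' @export
glance.herb_backbone <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    rule = x$rule,
    n_edges = nrow(x$edges),
    n_retained = sum(x$edges$retained),
    n_degree_one = sum(x$edges$degree_one)
  )
}

#' Core subgraph of the backbone
#'
#' Nodes whose degree in the original weighted graph reaches `min_degree`,
#' together with the retained backbone edges among them — the putative core
#' prescription.
#'
#' @param b A `herb_backbone`.
#' @param min_degree Minimum raw-graph degree (default 36).
#' @return List with `nodes` (tibble `herb`, `degree`, `strength`, `count`)
#'   and `edges` (retained backbone edges with both endpoints in the core).
#' @export
core_subgraph <- function(b, min_degree = 36) {
  stopifnot(inherits(b, "herb_backbone"))
  nodes <- b$graph$nodes |> filter(.data$degree >= min_degree)
  keep <- nodes$herb
  edges <- b$edges |>
    filter(.data$retained, .data$herb_a %in% keep, .data$herb_b %in% keep)
  list(nodes = nodes, edges = edges)
}

#' Export a graph or backbone
#'
#' `write_edge_list()` writes a weighted edge-list CSV (for a backbone the
#' columns include each endpoint's disparity score and the retention flag);
#' `write_graphml()` writes GraphML via igraph.
#'
#' @param x A `herb_graph` or `herb_backbone`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  readr::write_csv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(x, path) {
  ig <- as_igraph(x)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Convert to an igraph object
#'
#' @param x A `herb_graph` or `herb_backbone` (backbones keep only retained
#'   edges, with `alpha_score` as an edge attribute).
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "herb_backbone")) {
    edges <- x$edges |> filter(.data$retained)
    ig <- igraph::graph_from_data_frame(
      edges |> select("herb_a", "herb_b", "weight", "alpha_score"),
      directed = FALSE,
      vertices = x$graph$nodes
    )
  } else if (inherits(x, "herb_graph")) {
    ig <- igraph::graph_from_data_frame(
      x$edges, directed = FALSE, vertices = x$nodes
    )
  } else {
    stop_herbminer("expected a herb_graph or herb_backbone", "herbminer_bad_input")
  }
  ig
}

#' Network plot of a backbone
#'
#' Retained edges drawn on a force-directed layout, edge width proportional
#' to co-prescription weight.
#'
#' @param object A `herb_backbone`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herb_backbone <- function(object, ...) {
  ig <- as_igraph(object)
  set.seed(1)  # layout only; analysis results carry their own seeds
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(
    herb = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]
  )
  e <- igraph::as_data_frame(ig, what = "edges")
  seg <- tibble(
    x = nodes$x[match(e$from, nodes$herb)],
    y = nodes$y[match(e$from, nodes$herb)],
    xend = nodes$x[match(e$to, nodes$herb)],
    yend = nodes$y[match(e$to, nodes$herb)],
    weight = e$weight
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3, colour = "#4C72B0") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$herb),
                       vjust = -1, size = 2.8) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
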