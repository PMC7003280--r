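#' Select high-frequency herbs
#'
#' Herbs prescribed strictly more than `min_count` times, ordered by count
#' descending (ties by name). The default threshold of 30 reflects the
#' convention of clustering only the core, habitually prescribed herbs.
#'
#' @param db A `transaction_db`.
#' @param min_count Strict lower bound on the occurrence count (default 30).
#' @return Character vector of herb names.
#' @export
select_high_frequency <- function(db, min_count = 30) {
  counts <- item_counts(db)
  counts$herb[counts$count > min_count]
}

#' Euclidean distances between herb incidence profiles
#'
#' Each herb is represented by its binary incidence vector over the
#' transactions (1 if prescribed in that transaction); the distance between
#' two herbs is the Euclidean norm of the difference, so the squared
#' distance equals the number of prescriptions containing exactly one of
#' the two herbs (the Hamming distance of the binary profiles).
#'
#' @param db A `transaction_db`.
#' @param herbs Herbs to include (default: all items). Order is preserved in
#'   the result's labels.
#' @return A [stats::dist] object labelled by herb.
#' @export
herb_distances <- function(db, herbs = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  herbs <- herbs %||% db$items
  unknown <- setdiff(herbs, db$items)
  if (length(unknown) > 0) {
    stop_herbminer(paste0("herb(s) not in database: ",
                          paste(unknown, collapse = ", ")),
                   "herbminer_unknown_herb")
  }
  m <- db$incidence[herbs, , drop = FALSE] * 1
  dist(m, method = "euclidean")
}

#' Agglomerative hierarchical clustering of herbs
#'
#' Standard bottom-up merging: every herb starts as its own cluster and the
#' two closest clusters are merged repeatedly under the chosen linkage.
#' Ward's method (on squared Euclidean distances, `ward.D2`) is the default;
#' complete and average linkage are available. All three linkages are
#' monotone, so merge heights are nondecreasing. Ties between equally close
#' pairs are broken toward the pair with the lowest label indices, making
#' dendrograms reproducible.
#'
#' @param d A [stats::dist] from [herb_distances()] (or any labelled dist).
#' @param linkage `"ward"`, `"complete"`, or `"average"`.
#' @return An object of class `herb_dendrogram` wrapping the
#'   [stats::hclust] merge tree.
#' @export
agglomerate <- function(d, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (attr(d, "Size") < 2) {
    stop_herbminer("clustering needs at least 2 herbs", "herbminer_too_few_items")
  }
  method <- switch(linkage, ward = "ward.D2", complete = "complete",
                   average = "average")
  hc <- hclust(d, method = method)
  structure(list(hclust = hc, linkage = linkage), class = "herb_dendrogram")
}

#' @export
print.herb_dendrogram <- function(x, ...) {
  cat("<herb_dendrogram>", length(x$hclust$labels), "herbs,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' @export
tidy.herb_dendrogram <- function(x, ...) {
  hc <- x$hclust
  tibble(
    step = seq_len(nrow(hc$merge)),
    cluster_a = hc$merge[, 1],
    cluster_b = hc$merge[, 2],
    height = hc$height
  )
}

#' @export
glance.herb_dendrogram <- function(x, ...) {
  tibble(
    n_leaves = length(x$hclust$labels),
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro A `herb_dendrogram` from [agglomerate()].
#' @param k Number of clusters (default 5), between 1 and the number of
#'   leaves.
#' @return Tibble with columns `herb`, `cluster` (integer ids 1..k; exactly
#'   `k` nonempty clusters).
#' @export
cut_dendrogram <- function(dendro, k = 5) {
  stopifnot(inherits(dendro, "herb_dendrogram"))
  n_leaves <- length(dendro$hclust$labels)
  if (k < 1 || k > n_leaves) {
    stop_herbminer(paste0("k must be between 1 and ", n_leaves),
                   "herbminer_bad_k")
  }
  assignment <- cutree(dendro$hclust, k = k)
  tibble(herb = names(assignment), cluster = unname(assignment))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights, so the tree can be
#' rendered by any phylogenetics viewer.
#'
#' @param dendro A `herb_dendrogram`.
#' @param path Optional file to write the string to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "herb_dendrogram"))
  phy <- ape::as.phylo(dendro$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Dendrogram plot of a herb clustering
#'
#' @param object A `herb_dendrogram`.
#' @param k Optional number of clusters to mark with a cut line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herb_dendrogram <- function(object, k = NULL, ...) {
  hc <- object$hclust
  seg <- dendrogram_segments(hc)
  lab <- tibble(
    x = seq_along(hc$order),
    label = hc$labels[hc$order]
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1, size = 2.6
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "Merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(k) && k > 1) {
    cut_h <- mean(rev(hc$height)[c(k - 1, k)])
    p <- p + ggplot2::geom_hline(yintercept = cut_h, linetype = "dashed",
                                 colour = "#C44E52")
  }
  p
}

# segment coordinates for a base-graphics-free dendrogram rendering
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  pos <- numeric(n)                     # leaf x-positions in plotting order
  pos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  segs <- list()
  coord <- function(id) {
    if (id < 0) c(pos[-id], 0) else c(node_x[id], node_y[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- coord(hc$merge[i, 1])
    b <- coord(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    h <- hc$height[i]
    segs[[length(segs) + 1]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}
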