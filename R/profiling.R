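#' Herb frequency table
#'
#' Per-herb prescription counts with relative frequency (count over the
#' number of transactions, rounded half-up to 3 decimals), restricted to
#' herbs reaching `min_count`, sorted by count descending then name.
#'
#' @param db A `transaction_db`.
#' @param min_count Minimum occurrence count for inclusion (default 1).
#' @return Tibble with columns `herb`, `count`, `relative_frequency`.
#' @export
herb_frequency <- function(db, min_count = 1) {
  n <- n_transactions(db)
  item_counts(db) |>
    filter(.data$count >= min_count) |>
    mutate(relative_frequency = round_half_up(.data$count / n, 3))
}

#' Attribute distribution of prescribed herbs
#'
#' Distribution of a herb attribute (four-natures property, taste, meridian
#' tropism, or action category) across all herb occurrences in the database.
#' Each level's weighted count sums the occurrence counts of the herbs
#' carrying that level, so a herb prescribed 100 times contributes 100 to
#' each of its levels; the rate is the weighted count over the total number
#' of herb occurrences, as a percentage rounded half-up to 2 decimals.
#'
#' Property and category are single-valued, so their weighted counts sum
#' exactly to the total occurrences and rates sum to 100 up to rounding.
#' Tastes and meridians are multi-valued, so their weighted counts may exceed
#' the total. Set `weighted = FALSE` to count each distinct herb once instead
#' of once per occurrence.
#'
#' @param db A `transaction_db`.
#' @param kb A `herb_kb` covering every herb in `db`.
#' @param kind One of `"property"`, `"taste"`, `"meridian"`, `"category"`.
#' @param weighted Weight levels by herb occurrence counts (default) or count
#'   each herb once.
#' @return Tibble with columns `level`, `weighted_count`, `rate_pct`, sorted
#'   by weighted count descending then level.
#' @examples
#' kb <- read_knowledge_base(herbminer_example("herb_kb.csv"))
#' recs <- read_prescriptions(herbminer_example("example_prescriptions.csv"))
#' db <- standardize_prescriptions(recs, kb)
#' attribute_profile(db, kb, "category")
#' @export
attribute_profile <- function(db, kb,
                              kind = c("property", "taste", "meridian", "category"),
                              weighted = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(db, "transaction_db"), inherits(kb, "herb_kb"))

  counts <- item_counts(db)
  missing <- setdiff(counts$herb, kb$records$canonical_name)
  if (length(missing) > 0) {
    stop_herbminer(
      paste0("herb(s) in database but not in knowledge base: ",
             paste(head(missing, 5), collapse = ", ")),
      "herbminer_unknown_herb"
    )
  }

  rec <- kb$records[match(counts$herb, kb$records$canonical_name), ]
  levels_per_herb <- switch(
    kind,
    property = as.list(rec$property),
    taste    = rec$tastes,
    meridian = rec$meridians,
    category = as.list(rec$category)
  )

  w <- if (weighted) counts$count else rep(1L, nrow(counts))
  total <- sum(w)
  long <- tibble(
    level = unlist(levels_per_herb),
    w = rep(w, times = purrr::map_int(levels_per_herb, length))
  ) |>
    filter(!is.na(.data$level))

  long |>
    group_by(.data$level) |>
    summarise(weighted_count = sum(.data$w), .groups = "drop") |>
    mutate(rate_pct = round_half_up(100 * .data$weighted_count / total, 2)) |>
    arrange(desc(.data$weighted_count), .data$level)
}

#' Bar chart of a herb frequency table
#'
#' @param tab Tibble from [herb_frequency()].
#' @param top_n Show at most this many herbs.
#' @return A ggplot object.
#' @export
plot_herb_frequency <- function(tab, top_n = 20) {
  tab <- head(tab, top_n)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$herb, .data$count), y = .data$count
  )) +
    ggplot2::geom_col(fill = "#4C72B0") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prescriptions containing herb") +
    ggplot2::theme_minimal()
}

#' Bar chart of an attribute profile
#'
#' @param profile Tibble from [attribute_profile()].
#' @return A ggplot object.
#' @export
plot_attribute_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = stats::reorder(.data$level, .data$weighted_count),
    y = .data$weighted_count
  )) +
    ggplot2::geom_col(fill = "#55A868") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Weighted occurrence count") +
    ggplot2::theme_minimal()
}
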