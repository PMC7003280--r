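#' Level-wise Apriori frequent-itemset mining
#'
#' Finds every herb itemset whose support (fraction of transactions
#' containing all of its items) reaches `min_support`, by level-wise
#' candidate generation: frequent k-itemsets are joined on a shared
#' (k-1)-prefix to propose (k+1)-candidates, candidates with any infrequent
#' k-subset are pruned before counting (anti-monotonicity of support), and
#' the search stops when a level produces no frequent sets. No maximum
#' itemset length is imposed; the level-wise search terminates naturally.
#'
#' @param db A `transaction_db`.
#' @param min_support Minimum support as a fraction in (0, 1].
#' @return A tibble with one row per frequent itemset: `items` (list-column
#'   of sorted canonical names), `size`, `count` (transactions containing
#'   all items), `support` (count / n). Ordered by size, then
#'   lexicographically by items.
#' @examples
#' db <- build_exact_fixture(4, c(A = 4, B = 2, C = 1), list(list("A", "B", 2)))
#' frequent_itemsets(db, 0.5)
#' @export
frequent_itemsets <- function(db, min_support) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop_herbminer("min_support must be in (0, 1]", "herbminer_bad_threshold")
  }
  n <- n_transactions(db)
  if (n == 0) stop_herbminer("empty transaction database", "herbminer_empty_input")
  m <- db$incidence
  # support >= min_support  <=>  count >= min_support * n, with a guard
  # against representation error in the product
  min_count <- ceiling(min_support * n - 1e-9)

  counts1 <- rowSums(m)
  frequent <- list()
  level <- lapply(unname(which(counts1 >= min_count)), function(i) i)
  level_counts <- counts1[counts1 >= min_count]
  k <- 1
  while (length(level) > 0) {
    frequent[[k]] <- list(sets = level, counts = as.integer(level_counts))
    cands <- apriori_candidates(level)
    if (length(cands) == 0) break
    cnt <- vapply(cands, function(s) sum(colSums(m[s, , drop = FALSE]) == length(s)),
                  numeric(1))
    keep <- cnt >= min_count
    level <- cands[keep]
    level_counts <- cnt[keep]
    k <- k + 1
  }

  rows <- purrr::map(frequent, function(lv) {
    tibble(
      items = purrr::map(lv$sets, ~ db$items[.x]),
      size = purrr::map_int(lv$sets, length),
      count = lv$counts
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(items = list(), size = integer(0), count = integer(0),
                  support = numeric(0)))
  }
  out$support <- out$count / n
  key <- purrr::map_chr(out$items, paste, collapse = "\r")
  out[order(out$size, key, method = "radix"), ] |> as_tibble()
}

# join frequent k-itemsets sharing their first k-1 indices; prune candidates
# with an infrequent k-subset
apriori_candidates <- function(level) {
  k <- length(level[[1]])
  keys <- vapply(level, paste, character(1), collapse = ",")
  have <- new.env(hash = TRUE, size = max(16L, length(level)))
  for (kk in keys) assign(kk, TRUE, envir = have)

  prefix <- vapply(level, function(s) paste(s[-k], collapse = ","), character(1))
  groups <- split(seq_along(level), prefix)
  cands <- list()
  for (g in groups) {
    if (length(g) < 2) next
    # order members by last element so joins come out sorted
    g <- g[order(vapply(level[g], function(s) s[k], numeric(1)))]
    for (a in seq_len(length(g) - 1)) {
      for (b in seq((a + 1), length(g))) {
        cand <- c(level[[g[a]]], level[[g[b]]][k])
        ok <- TRUE
        for (drop in seq_len(k + 1)) {
          sub <- paste(cand[-drop], collapse = ",")
          if (!exists(sub, envir = have, inherits = FALSE)) { ok <- FALSE; break }
        }
        if (ok) cands[[length(cands) + 1]] <- cand
      }
    }
  }
  cands
}

#' Exhaustive frequent-itemset search (test oracle)
#'
#' Enumerates every nonempty subset of the item universe and keeps those
#' whose support reaches `min_support`. Exponential in the universe size, so
#' it refuses universes above 20 items; it exists as an independent oracle
#' against which the level-wise search is validated.
#'
#' @inheritParams frequent_itemsets
#' @return Same shape and ordering as [frequent_itemsets()].
#' @export
brute_force_frequent <- function(db, min_support) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop_herbminer("min_support must be in (0, 1]", "herbminer_bad_threshold")
  }
  p <- length(db$items)
  if (p > 20) {
    stop_herbminer("brute-force search limited to item universes of at most 20",
                   "herbminer_universe_too_large")
  }
  n <- n_transactions(db)
  if (n == 0) stop_herbminer("empty transaction database", "herbminer_empty_input")
  min_count <- ceiling(min_support * n - 1e-9)

  # bitmask encoding: transaction t -> integer with bit i set iff item i present
  tmask <- as.integer(colSums(db$incidence * 2^(seq_len(p) - 1)))
  out <- list()
  for (s in seq_len(2^p - 1)) {
    cnt <- sum(bitwAnd(tmask, s) == s)
    if (cnt >= min_count) {
      idx <- which(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
      out[[length(out) + 1]] <- list(items = db$items[idx], count = cnt)
    }
  }
  if (length(out) == 0) {
    return(tibble(items = list(), size = integer(0), count = integer(0),
                  support = numeric(0)))
  }
  res <- tibble(
    items = purrr::map(out, "items"),
    size = purrr::map_int(out, ~ length(.x$items)),
    count = purrr::map_int(out, ~ as.integer(.x$count)),
    support = purrr::map_int(out, ~ as.integer(.x$count)) / n
  )
  key <- purrr::map_chr(res$items, paste, collapse = "\r")
  res[order(res$size, key, method = "radix"), ]
}

#' Association-rule metrics
#'
#' Support, confidence and lift of a rule X => Y from the four counts:
#' support = sigma(X u Y) / N, confidence = sigma(X u Y) / sigma(X), and
#' lift = confidence divided by the relative frequency of Y (lift > 1 means
#' Y is over-represented when X is prescribed). Support and confidence are
#' reported as percentages; all three are rounded half-up to 2 decimals at
#' reporting time only.
#'
#' @param count_xy Transactions containing all of X and Y.
#' @param count_x Transactions containing X.
#' @param count_y Transactions containing Y.
#' @param n Total transactions.
#' @return A tibble with one row: `support_pct`, `confidence_pct`, `lift`.
#' @examples
#' rule_metrics(154, 174, 231, 299)
#' @export
rule_metrics <- function(count_xy, count_x, count_y, n) {
  if (count_x <= 0 || count_y <= 0) {
    stop_herbminer("antecedent and consequent counts must be positive",
                   "herbminer_bad_counts")
  }
  if (count_xy > min(count_x, count_y) || max(count_x, count_y) > n) {
    stop_herbminer(
      "counts must satisfy count_xy <= min(count_x, count_y) <= n",
      "herbminer_bad_counts"
    )
  }
  confidence <- count_xy / count_x
  tibble(
    support_pct = round_half_up(100 * count_xy / n, 2),
    confidence_pct = round_half_up(100 * confidence, 2),
    lift = round_half_up(confidence / (count_y / n), 2)
  )
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every bipartition with a
#' consequent of at most `max_rhs` items, emits the rule LHS => RHS whenever
#' its (unrounded) confidence reaches `min_confidence`. Consequents default
#' to single herbs, the form in which herb pairs are read clinically.
#'
#' @param itemsets Output of [frequent_itemsets()] on `db`.
#' @param db The `transaction_db` the itemsets were mined from.
#' @param min_confidence Minimum confidence as a fraction in (0, 1].
#' @param max_rhs Maximum consequent size (default 1).
#' @return A tibble with columns `lhs` and `rhs` (list-columns of canonical
#'   names), `lhs_label`/`rhs_label` (`;`-joined), `support_pct`,
#'   `confidence_pct`, `lift` (rounded half-up to 2 decimals), and `n`.
#'   Ordered by support descending, then labels.
#' @export
generate_rules <- function(itemsets, db, min_confidence, max_rhs = 1) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_confidence) || min_confidence <= 0 || min_confidence > 1) {
    stop_herbminer("min_confidence must be in (0, 1]", "herbminer_bad_threshold")
  }
  n <- n_transactions(db)
  empty <- tibble(
    lhs = list(), rhs = list(), lhs_label = character(0), rhs_label = character(0),
    support_pct = numeric(0), confidence_pct = numeric(0), lift = numeric(0),
    n = integer(0)
  )
  if (nrow(itemsets) == 0) return(empty)

  count_of <- setNames(itemsets$count,
                       purrr::map_chr(itemsets$items, paste, collapse = "\r"))
  lookup <- function(items) unname(count_of[[paste(items, collapse = "\r")]])

  rows <- list()
  big <- itemsets[itemsets$size >= 2, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    items <- big$items[[i]]
    c_xy <- big$count[i]
    for (r in seq_len(min(max_rhs, length(items) - 1))) {
      rhs_sets <- utils::combn(items, r, simplify = FALSE)
      for (rhs in rhs_sets) {
        lhs <- setdiff(items, rhs)
        c_x <- lookup(lhs)
        c_y <- lookup(rhs)
        conf <- c_xy / c_x
        if (conf >= min_confidence - 1e-12) {
          lhs_lab <- paste(lhs, collapse = ";")
          rhs_lab <- paste(rhs, collapse = ";")
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble(lhs = list(lhs), rhs = list(rhs),
                   lhs_label = lhs_lab, rhs_label = rhs_lab),
            rule_metrics(c_xy, c_x, c_y, n),
            tibble(n = n)
          )
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows) |>
    arrange(desc(.data$support_pct), .data$lhs_label, .data$rhs_label)
}

#' Check reported rule metrics against marginal counts
#'
#' Given a table of reported rules (support, confidence, lift as printed in
#' a summary table) and the per-herb marginal counts, reconstructs the
#' implied integer joint count from each rule's support, recomputes
#' confidence (where the antecedent is a single herb with a known marginal)
#' and lift (from the reported confidence and the consequent's marginal),
#' and flags rows whose reported metrics are not reproducible under the
#' support/confidence/lift definitions. Published rule tables are sometimes
#' internally inconsistent at the printed precision; this report enumerates
#' such rows instead of papering over them.
#'
#' @param reported Tibble with columns `lhs_label`, `rhs_label`
#'   (`;`-separated names), `support_pct`, `confidence_pct`, `lift`.
#' @param marginals Tibble with columns `herb`, `count` (known marginals; the
#'   consequent of every rule must be present).
#' @param n Total transaction count behind the reported table.
#' @return The input with added columns `implied_joint` (integer nearest to
#'   support * n / 100), `recomputed_confidence_pct` (NA when the antecedent
#'   marginal is unknown), `recomputed_lift`, and logical flags
#'   `confidence_consistent`, `lift_consistent`.
#' @export
rule_consistency_report <- function(reported, marginals, n) {
  marg <- setNames(marginals$count, marginals$herb)
  get_marg <- function(label) {
    herbs <- split_field(label)
    if (length(herbs) == 1 && herbs %in% names(marg)) unname(marg[herbs]) else NA_integer_
  }
  reported |>
    mutate(
      implied_joint = as.integer(round_half_up(.data$support_pct * n / 100)),
      lhs_count = purrr::map_int(.data$lhs_label, ~ as.integer(get_marg(.x))),
      rhs_count = purrr::map_int(.data$rhs_label, ~ as.integer(get_marg(.x))),
      recomputed_confidence_pct = ifelse(
        is.na(.data$lhs_count), NA_real_,
        round_half_up(100 * .data$implied_joint / .data$lhs_count, 2)
      ),
      recomputed_lift = round_half_up(
        (.data$confidence_pct / 100) / (.data$rhs_count / n), 2
      ),
      confidence_consistent = is.na(.data$recomputed_confidence_pct) |
        abs(.data$recomputed_confidence_pct - .data$confidence_pct) < 0.005,
      lift_consistent = abs(.data$recomputed_lift - .data$lift) < 0.005
    ) |>
    select(-"lhs_count", -"rhs_count")
}

#' Export association rules as CSV
#'
#' Writes `lhs` (`;`-separated), `rhs`, `support_pct`, `confidence_pct`,
#' `lift`, `n` — the layout of a standard herb-pair rule table.
#'
#' @param rules Tibble from [generate_rules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  rules |>
    select(lhs = "lhs_label", rhs = "rhs_label",
           "support_pct", "confidence_pct", "lift", "n") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Scatterplot of mined rules
#'
#' Support against confidence, points coloured by lift — the standard
#' two-threshold view of a rule set.
#'
#' @param rules Tibble from [generate_rules()].
#' @return A ggplot object.
#' @export
plot_rules <- function(rules) {
  ggplot2::ggplot(rules, ggplot2::aes(
    x = .data$support_pct, y = .data$confidence_pct, colour = .data$lift
  )) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "Support (%)", y = "Confidence (%)", colour = "Lift") +
    ggplot2::theme_minimal()
}
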