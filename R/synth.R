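#' Configuration for synthetic prescription generation
#'
#' Collects and validates the parameters of the two generators. For the
#' independence model only `marginals` is used; for the template-mixture
#' model, `templates` (named numeric vectors: herb -> per-transaction
#' inclusion probability given the template is drawn), `mixture_weights`,
#' and optionally `noise_herbs`/`noise_rate` (each noise herb is added to
#' any transaction independently with probability `noise_rate`). A herb
#' present in every template plays the role of a planted core herb.
#'
#' All randomness flows from `seed`; the caller's random-number state is
#' saved and restored, so generation never perturbs other code.
#'
#' @param n_transactions Number of prescriptions to generate.
#' @param marginals Named numeric vector of per-herb inclusion probabilities
#'   (independence model).
#' @param templates List of named numeric vectors (template-mixture model).
#' @param mixture_weights Numeric vector of template probabilities, summing
#'   to 1; defaults to uniform.
#' @param noise_herbs Character vector of background herbs.
#' @param noise_rate Per-herb, per-transaction inclusion probability for
#'   noise herbs.
#' @param seed Integer seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_transactions, marginals = NULL, templates = NULL,
                         mixture_weights = NULL, noise_herbs = character(0),
                         noise_rate = 0, seed = 1) {
  stopifnot(is.numeric(n_transactions), n_transactions >= 1)
  if (!is.null(marginals)) {
    if (is.null(names(marginals)) || any(!nzchar(names(marginals)))) {
      stop_herbminer("marginals must be a named vector", "herbminer_bad_config")
    }
    if (any(marginals < 0 | marginals > 1)) {
      stop_herbminer("marginal probabilities must lie in [0, 1]",
                     "herbminer_bad_config")
    }
  }
  if (!is.null(templates)) {
    ok <- purrr::map_lgl(templates, ~ is.numeric(.x) && !is.null(names(.x)) &&
                           all(.x >= 0 & .x <= 1))
    if (length(templates) == 0 || !all(ok)) {
      stop_herbminer(
        "templates must be named numeric vectors of probabilities in [0, 1]",
        "herbminer_bad_config"
      )
    }
    mixture_weights <- mixture_weights %||%
      rep(1 / length(templates), length(templates))
    if (length(mixture_weights) != length(templates) ||
        abs(sum(mixture_weights) - 1) > 1e-8 || any(mixture_weights < 0)) {
      stop_herbminer("mixture_weights must be nonnegative and sum to 1",
                     "herbminer_bad_config")
    }
  }
  if (noise_rate < 0 || noise_rate > 1) {
    stop_herbminer("noise_rate must lie in [0, 1]", "herbminer_bad_config")
  }
  structure(
    list(
      n_transactions = as.integer(n_transactions),
      marginals = marginals,
      templates = templates,
      mixture_weights = mixture_weights,
      noise_herbs = noise_herbs,
      noise_rate = noise_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# run code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

transaction_ids_for <- function(n) sprintf("t%04d", seq_len(n))

#' Generate prescriptions under the independence model
#'
#' Every herb enters every transaction independently with its marginal
#' probability — the null model with no association structure, used to
#' check that the rule miner reports nothing that the marginals alone do
#' not imply.
#'
#' @param cfg A `synth_config` with `marginals` set.
#' @return A `transaction_db` with `cfg$n_transactions` transactions; the
#'   same config (same seed) always reproduces it exactly.
#' @export
generate_independent <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(cfg$marginals)) {
    stop_herbminer("independence model needs marginals", "herbminer_bad_config")
  }
  herbs <- sort_c(names(cfg$marginals))
  p <- cfg$marginals[herbs]
  n <- cfg$n_transactions
  inc <- with_local_seed(cfg$seed, {
    matrix(stats::runif(length(herbs) * n) < rep(p, times = n),
           nrow = length(herbs),
           dimnames = list(herbs, transaction_ids_for(n)))
  })
  transaction_db(inc)
}

#' Generate prescriptions from a mixture of herb templates
#'
#' Each transaction first draws a latent template (a syndrome-style
#' co-prescription pattern) according to the mixture weights, then includes
#' each of that template's herbs with its inclusion probability, and finally
#' adds each noise herb independently with the noise rate. Herbs shared by
#' all templates behave as a planted prescription core: they are frequent,
#' densely co-prescribed, and recoverable by the backbone analysis; herbs
#' exclusive to one template form planted clusters recoverable by the
#' hierarchical clustering.
#'
#' @param cfg A `synth_config` with `templates` set.
#' @return A list with `db` (the `transaction_db`) and `truth`, a
#'   `planted_truth` list carrying `template_of` (tibble `prescription_id`,
#'   `template`), `core_herbs` (herbs present in every template),
#'   `template_herbs` (per-template herb sets) and `high_lift_pairs`
#'   (tibble of within-template pairs).
#' @export
generate_template_mixture <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(cfg$templates)) {
    stop_herbminer("template-mixture model needs templates", "herbminer_bad_config")
  }
  n <- cfg$n_transactions
  herbs <- sort_c(unique(c(unlist(purrr::map(cfg$templates, names)), cfg$noise_herbs)))
  n_t <- length(cfg$templates)

  res <- with_local_seed(cfg$seed, {
    z <- sample.int(n_t, n, replace = TRUE, prob = cfg$mixture_weights)
    inc <- matrix(FALSE, nrow = length(herbs), ncol = n,
                  dimnames = list(herbs, transaction_ids_for(n)))
    for (j in seq_len(n)) {
      tpl <- cfg$templates[[z[j]]]
      drawn <- names(tpl)[stats::runif(length(tpl)) < tpl]
      if (length(cfg$noise_herbs) > 0 && cfg$noise_rate > 0) {
        drawn <- c(drawn, cfg$noise_herbs[
          stats::runif(length(cfg$noise_herbs)) < cfg$noise_rate])
      }
      inc[unique(drawn), j] <- TRUE
    }
    list(z = z, inc = inc)
  })

  core <- Reduce(intersect, purrr::map(cfg$templates, names))
  pair_rows <- purrr::imap(cfg$templates, function(tpl, i) {
    hs <- sort_c(names(tpl))
    if (length(hs) < 2) return(NULL)
    cmb <- utils::combn(hs, 2)
    tibble(herb_a = cmb[1, ], herb_b = cmb[2, ], template = as.integer(i))
  })

  truth <- structure(
    list(
      template_of = tibble(prescription_id = transaction_ids_for(n),
                           template = res$z),
      core_herbs = sort_c(core),
      template_herbs = purrr::map(cfg$templates, ~ sort_c(names(.x))),
      high_lift_pairs = dplyr::bind_rows(pair_rows)
    ),
    class = "planted_truth"
  )
  list(db = transaction_db(res$inc), truth = truth)
}

#' Deterministic transaction database with exact marginal and pair counts
#'
#' Constructs a database of `n` transactions in which every herb appears
#' exactly its specified number of times and every constrained pair
#' co-occurs exactly its specified number of times. Used to realize count
#' configurations reconstructed from published summary tables, so that
#' downstream metrics can be checked against printed values.
#'
#' Construction is a circular interval arrangement: transactions are points
#' on a ring of size `n` and each herb occupies a contiguous arc of length
#' equal to its marginal count. Arcs are placed by traversing each connected
#' component of the pair-constraint graph from its lexicographically first
#' herb, offsetting each child's arc against its parent's so the arcs
#' overlap in exactly the constrained number of transactions. The placement
#' is purely deterministic (no search, no randomness), and is exact for any
#' constraint set that forms a forest and respects the Frechet bounds
#' `max(0, cA + cB - n) <= cAB <= min(cA, cB)`; constraint graphs with
#' cycles are rejected.
#'
#' @param n Number of transactions.
#' @param marginal_counts Named integer vector, herb -> occurrence count
#'   (each between 0 and `n`).
#' @param pair_constraints List of `list(herb_a, herb_b, count)` triples (or
#'   a tibble with those columns); may be empty.
#' @return A `transaction_db` whose [item_counts()] and [pair_counts()]
#'   reproduce the requested numbers exactly.
#' @examples
#' db <- build_exact_fixture(
#'   299,
#'   c("Rhizoma Dioscoreae" = 231, "Radix Astragali" = 174),
#'   list(list("Rhizoma Dioscoreae", "Radix Astragali", 154))
#' )
#' item_counts(db)
#' @export
build_exact_fixture <- function(n, marginal_counts, pair_constraints = list()) {
  n <- as.integer(n)
  stopifnot(n >= 1, is.numeric(marginal_counts), !is.null(names(marginal_counts)))
  counts <- as.integer(marginal_counts)
  names(counts) <- names(marginal_counts)
  if (any(counts < 0 | counts > n)) {
    stop_herbminer("marginal counts must lie in [0, n]", "herbminer_infeasible")
  }

  cons <- normalize_pair_constraints(pair_constraints)
  if (nrow(cons) > 0) {
    unknown <- setdiff(unique(c(cons$herb_a, cons$herb_b)), names(counts))
    if (length(unknown) > 0) {
      stop_herbminer(paste0("pair constraint references unknown herb(s): ",
                            paste(unknown, collapse = ", ")),
                     "herbminer_infeasible")
    }
    lo <- pmax(0L, counts[cons$herb_a] + counts[cons$herb_b] - n)
    hi <- pmin(counts[cons$herb_a], counts[cons$herb_b])
    bad <- cons$count < lo | cons$count > hi
    if (any(bad)) {
      i <- which(bad)[1]
      stop_herbminer(
        paste0("infeasible pair constraint (", cons$herb_a[i], ", ",
               cons$herb_b[i], "): requested ", cons$count[i],
               " outside Frechet bounds [", lo[i], ", ", hi[i], "]"),
        "herbminer_infeasible"
      )
    }
    check_forest(cons, names(counts))
  }

  start <- setNames(rep(NA_integer_, length(counts)), names(counts))
  adj <- constraint_adjacency(cons)
  for (root in sort_c(names(counts))) {
    if (!is.na(start[root])) next
    start[root] <- 0L
    queue <- root
    while (length(queue) > 0) {
      h <- queue[[1]]
      queue <- queue[-1]
      for (nb in sort_c(adj[[h]] %||% character(0))) {
        if (!is.na(start[nb])) next
        c_ab <- cons$count[(cons$herb_a == h & cons$herb_b == nb) |
                           (cons$herb_a == nb & cons$herb_b == h)]
        start[nb] <- (start[h] + counts[h] - c_ab) %% n
        queue <- c(queue, nb)
      }
    }
  }

  herbs <- sort_c(names(counts))
  inc <- matrix(FALSE, nrow = length(herbs), ncol = n,
                dimnames = list(herbs, transaction_ids_for(n)))
  for (h in herbs) {
    if (counts[h] == 0) next
    pos <- ((start[h] + seq_len(counts[h]) - 1L) %% n) + 1L
    inc[h, pos] <- TRUE
  }
  db <- transaction_db(inc)

  # defensive verification: the arrangement must reproduce every requested count
  got <- setNames(item_counts(db)$count, item_counts(db)$herb)
  stopifnot(all(got[names(counts)] == counts))
  if (nrow(cons) > 0) {
    pc <- pair_counts(db)
    for (i in seq_len(nrow(cons))) {
      a <- min(cons$herb_a[i], cons$herb_b[i])
      b <- max(cons$herb_a[i], cons$herb_b[i])
      hit <- pc$count[pc$herb_a == a & pc$herb_b == b]
      got_pair <- if (length(hit) == 0) 0L else hit
      stopifnot(got_pair == cons$count[i])
    }
  }
  db
}

normalize_pair_constraints <- function(pair_constraints) {
  if (is.data.frame(pair_constraints)) {
    cons <- tibble(herb_a = as.character(pair_constraints$herb_a),
                   herb_b = as.character(pair_constraints$herb_b),
                   count = as.integer(pair_constraints$count))
  } else {
    cons <- dplyr::bind_rows(purrr::map(pair_constraints, function(p) {
      tibble(herb_a = as.character(p[[1]]), herb_b = as.character(p[[2]]),
             count = as.integer(p[[3]]))
    }))
  }
  if (nrow(cons) == 0) {
    return(tibble(herb_a = character(0), herb_b = character(0), count = integer(0)))
  }
  if (any(cons$herb_a == cons$herb_b)) {
    stop_herbminer("pair constraints must involve two distinct herbs",
                   "herbminer_infeasible")
  }
  key <- paste(pmin(cons$herb_a, cons$herb_b), pmax(cons$herb_a, cons$herb_b))
  if (anyDuplicated(key)) {
    stop_herbminer("duplicate pair constraint", "herbminer_infeasible")
  }
  cons
}

constraint_adjacency <- function(cons) {
  adj <- list()
  for (i in seq_len(nrow(cons))) {
    a <- cons$herb_a[i]; b <- cons$herb_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# the interval arrangement is exact only on forests; reject cycles
check_forest <- function(cons, herbs) {
  parent <- seq_along(herbs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(cons))) {
    ra <- find(match(cons$herb_a[i], herbs))
    rb <- find(match(cons$herb_b[i], herbs))
    if (ra == rb) {
      stop_herbminer(
        paste0("pair constraints form a cycle through '", cons$herb_a[i],
               "' and '", cons$herb_b[i],
               "'; only forest-shaped constraint sets are supported"),
        "herbminer_constraint_topology"
      )
    }
    parent[ra] <- rb
  }
  invisible(TRUE)
}
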