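#' Construct a transaction database
#'
#' The binary prescription-by-herb incidence structure that every downstream
#' stage (profiling, rule mining, clustering, network analysis) consumes.
#' Items are sorted lexicographically (C collation) so all outputs are
#' deterministic; incidence is a logical matrix with herbs in rows and
#' transactions (prescriptions) in columns, so duplicate herbs within a
#' prescription are impossible by construction.
#'
#' @param incidence Logical matrix, herbs x transactions, with herb names as
#'   rownames and transaction ids as colnames.
#' @return A `transaction_db` object.
#' @export
transaction_db <- function(incidence) {
  stopifnot(is.matrix(incidence), is.logical(incidence),
            !is.null(rownames(incidence)), !is.null(colnames(incidence)))
  ord <- order_c(rownames(incidence))
  incidence <- incidence[ord, , drop = FALSE]
  structure(
    list(
      items = rownames(incidence),
      transaction_ids = colnames(incidence),
      incidence = incidence
    ),
    class = "transaction_db"
  )
}

# locale-independent lexicographic order
order_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(x)
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("<transaction_db>", length(x$transaction_ids), "transactions,",
      length(x$items), "items,", sum(x$incidence), "herb occurrences\n")
  invisible(x)
}

#' Number of transactions in a database
#' @param db A `transaction_db`.
#' @return Integer count of transactions.
#' @export
n_transactions <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  length(db$transaction_ids)
}

#' @export
as_tibble.transaction_db <- function(x, ...) {
  idx <- which(x$incidence, arr.ind = TRUE)
  tibble(
    prescription_id = x$transaction_ids[idx[, "col"]],
    herb = x$items[idx[, "row"]]
  ) |>
    arrange(.data$prescription_id, .data$herb)
}

#' @export
tidy.transaction_db <- function(x, ...) as_tibble(x)

#' Read prescription records
#'
#' Reads raw prescription records from a CSV with columns
#' `prescription_id, patient_id, herbs` (raw herb names `;`-separated) or
#' from JSON lines with the same keys (`herbs` as an array). Herb strings are
#' left untouched; standardization happens in
#' [standardize_prescriptions()].
#'
#' @param path File path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (extension-based).
#' @return A tibble with columns `prescription_id`, `patient_id` and a
#'   list-column `raw_herbs`.
#' @export
read_prescriptions <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_herbminer(paste0("prescriptions file not found: ", path),
                   "herbminer_missing_file")
  }
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("prescription_id", "patient_id", "herbs")
    if (!all(need %in% names(raw))) {
      stop_herbminer(paste0("prescriptions file must have columns: ",
                            paste(need, collapse = ", ")),
                     "herbminer_malformed_input")
    }
    tibble(
      prescription_id = raw$prescription_id,
      patient_id = raw$patient_id,
      raw_herbs = purrr::map(raw$herbs, split_field)
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- purrr::map(lines, jsonlite::fromJSON)
    tibble(
      prescription_id = purrr::map_chr(recs, "prescription_id"),
      patient_id = purrr::map_chr(recs, "patient_id"),
      raw_herbs = purrr::map(recs, ~ as.character(.x$herbs))
    )
  }
}

#' Standardize prescriptions into a transaction database
#'
#' For every prescription: resolve each raw herb name against the knowledge
#' base, decompose registered compound formulae into their constituent herbs,
#' and collapse duplicates so the prescription becomes a set of canonical
#' herbs. The unit of analysis is the prescription (one visit's formula), not
#' the patient.
#'
#' @param records Tibble of prescription records as returned by
#'   [read_prescriptions()] (columns `prescription_id`, `raw_herbs`;
#'   `patient_id` optional and carried as metadata only).
#' @param kb A `herb_kb`.
#' @param on_unknown `"error"` (default) aborts on the first unmappable herb
#'   string; `"skip"` drops unmappable strings and records them in the
#'   returned skip log. Prescriptions whose herbs are all dropped are removed.
#' @return A `transaction_db`. When `on_unknown = "skip"`, attribute
#'   `skip_log` holds a tibble of dropped names
#'   (`prescription_id`, `raw_name`).
#' @examples
#' kb <- read_knowledge_base(herbminer_example("herb_kb.csv"))
#' recs <- tibble::tibble(
#'   prescription_id = "p1", patient_id = "u1",
#'   raw_herbs = list(c("Huangqi", "huangqi", "Shanyao"))
#' )
#' db <- standardize_prescriptions(recs, kb)
#' item_counts(db)
#' @export
standardize_prescriptions <- function(records, kb, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(kb, "herb_kb"))
  if (is.null(records) || nrow(records) == 0) {
    stop_herbminer("no prescription records supplied", "herbminer_empty_input")
  }
  if (any(purrr::map_int(records$raw_herbs, length) == 0)) {
    stop_herbminer("a prescription record has an empty herb list",
                   "herbminer_malformed_input")
  }

  skip_log <- list()
  baskets <- purrr::map2(records$raw_herbs, records$prescription_id, function(raw, pid) {
    herbs <- character(0)
    for (nm in raw) {
      res <- tryCatch(decompose_compound(nm, kb), herbminer_unknown_herb = function(e) e)
      if (inherits(res, "herbminer_unknown_herb")) {
        if (on_unknown == "error") stop(res)
        skip_log[[length(skip_log) + 1]] <<- tibble(prescription_id = pid,
                                                    raw_name = res$raw_name)
      } else {
        herbs <- c(herbs, res)
      }
    }
    unique(herbs)
  })

  keep <- purrr::map_int(baskets, length) > 0
  if (!any(keep)) {
    stop_herbminer("all prescriptions were empty after standardization",
                   "herbminer_empty_input")
  }
  baskets <- baskets[keep]
  ids <- records$prescription_id[keep]

  items <- sort_c(unique(unlist(baskets)))
  inc <- matrix(FALSE, nrow = length(items), ncol = length(baskets),
                dimnames = list(items, ids))
  for (j in seq_along(baskets)) inc[baskets[[j]], j] <- TRUE

  db <- transaction_db(inc)
  attr(db, "skip_log") <- if (length(skip_log) > 0) {
    dplyr::bind_rows(skip_log)
  } else {
    tibble(prescription_id = character(0), raw_name = character(0))
  }
  db
}

sort_c <- function(x) x[order_c(x)]

#' Per-herb occurrence counts
#'
#' Number of transactions in which each herb appears (each prescription
#' contributes at most 1 per herb because prescriptions are de-duplicated
#' sets). Summed over herbs this gives the total herb occurrences in the
#' database.
#'
#' @param db A `transaction_db`.
#' @return A tibble with columns `herb`, `count`, sorted by count descending
#'   then herb name.
#' @export
item_counts <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  tibble(herb = db$items, count = as.integer(rowSums(db$incidence))) |>
    arrange(desc(.data$count), .data$herb)
}

#' Pairwise co-prescription counts
#'
#' Number of transactions containing both herbs of each unordered pair, for
#' every pair that co-occurs at least once. These counts are the edge weights
#' of the co-prescription network and the joint frequencies behind
#' association-rule support.
#'
#' @param db A `transaction_db`.
#' @return A tibble with columns `herb_a`, `herb_b` (with `herb_a < herb_b`
#'   lexicographically) and `count`, sorted by count descending then names.
#' @export
pair_counts <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  m <- db$incidence * 1L
  joint <- tcrossprod(m)             # herbs x herbs co-occurrence counts
  idx <- which(upper.tri(joint) & joint > 0, arr.ind = TRUE)
  tibble(
    herb_a = db$items[idx[, "row"]],
    herb_b = db$items[idx[, "col"]],
    count = as.integer(joint[idx])
  ) |>
    arrange(desc(.data$count), .data$herb_a, .data$herb_b)
}

#' Write / read transaction databases as plain text
#'
#' `write_transactions()` exports either a "basket" file (one transaction per
#' line, herbs `;`-separated, prefixed by the transaction id and a tab) or a
#' long-format CSV (`prescription_id,herb`). `read_transactions()` reads both
#' formats back; a basket/long round trip reproduces the database exactly.
#'
#' @param db A `transaction_db`.
#' @param path Output (or input) file path.
#' @param format `"basket"` or `"long"`.
#' @return `write_transactions()` returns `path` invisibly;
#'   `read_transactions()` returns a `transaction_db`.
#' @export
write_transactions <- function(db, path, format = c("basket", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(db, "transaction_db"))
  if (format == "basket") {
    lines <- purrr::map_chr(seq_along(db$transaction_ids), function(j) {
      herbs <- db$items[db$incidence[, j]]
      paste0(db$transaction_ids[j], "\t", paste(herbs, collapse = ";"))
    })
    writeLines(lines, path)
  } else {
    readr::write_csv(as_tibble(db), path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path, format = c("basket", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_herbminer(paste0("transactions file not found: ", path),
                   "herbminer_missing_file")
  }
  if (format == "basket") {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- purrr::map_chr(parts, 1)
    baskets <- purrr::map(parts, ~ split_field(.x[2]))
  } else {
    long <- readr::read_csv(path, col_types = "cc", progress = FALSE)
    ids <- unique(long$prescription_id)
    baskets <- purrr::map(ids, ~ long$herb[long$prescription_id == .x])
  }
  items <- sort_c(unique(unlist(baskets)))
  inc <- matrix(FALSE, nrow = length(items), ncol = length(ids),
                dimnames = list(items, ids))
  for (j in seq_along(baskets)) inc[unique(baskets[[j]]), j] <- TRUE
  transaction_db(inc)
}
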