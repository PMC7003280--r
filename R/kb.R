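#' Controlled vocabularies for herb attributes
#'
#' The four-natures property scale (with its five levels), the seven taste
#' labels, the twelve organ meridians, and the seventeen therapeutic action
#' categories used to annotate herbs. Knowledge-base validation accepts only
#' these levels.
#'
#' @name herb_vocabulary
#' @format Character vectors.
NULL

#' @rdname herb_vocabulary
#' @export
herb_properties <- c("cold", "cool", "neutral", "warm", "hot")

#' @rdname herb_vocabulary
#' @export
herb_tastes <- c("pungent", "sweet", "sour", "bitter", "salty", "bland", "astringent")

#' @rdname herb_vocabulary
#' @export
herb_meridians <- c(
  "Lung", "Large Intestine", "Stomach", "Spleen", "Heart", "Small Intestine",
  "Bladder", "Kidney", "Pericardium", "Sanjiao", "Gallbladder", "Liver"
)

#' @rdname herb_vocabulary
#' @export
herb_categories <- c(
  "deficiency-tonifying",
  "heat-clearing",
  "dampness-draining diuretic",
  "hemostatic",
  "astringent",
  "qi-regulating",
  "blood-activating and stasis-resolving",
  "cough-suppressing and panting-calming",
  "exterior-releasing",
  "digestant",
  "wind-dampness dispelling",
  "dampness-resolving",
  "purgative",
  "nerve-soothing",
  "interior-warming",
  "liver-wind calming",
  "antitoxin-insecticide-antipruritic"
)

#' Read a herb knowledge base
#'
#' Loads the canonical herb registry that drives terminology standardization:
#' one row per herb (canonical Latin pharmaceutical name, pinyin, aliases,
#' four-natures property, tastes, meridian tropisms, action category) plus
#' optional compound-formula rows whose `components` field lists the
#' constituent herbs the compound decomposes into.
#'
#' Lookup keys (canonical names, pinyin, aliases) are indexed after trimming
#' whitespace and case-folding; matching is otherwise exact. Romanization
#' variants are handled as explicit aliases, never by fuzzy matching, so that
#' a miskeyed name surfaces as an error instead of silently corrupting counts.
#'
#' @param path Path to the knowledge-base file.
#' @param format `"csv"` (columns `canonical_name, pinyin, aliases, property,
#'   tastes, meridians, category` and optionally `components`; multi-valued
#'   fields are `;`-separated) or `"json"` (an array of objects with the same
#'   keys, multi-valued fields as arrays). Guessed from the file extension by
#'   default.
#' @return A `herb_kb` object: a list with `records` (tibble of herb rows),
#'   `alias_index` (named character vector, normalized alias -> canonical
#'   name) and `compound_map` (named list, normalized compound name ->
#'   character vector of constituent canonical names).
#' @examples
#' kb <- read_knowledge_base(herbminer_example("herb_kb.csv"))
#' canonicalize("Huangqi", kb)
#' @export
read_knowledge_base <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_herbminer(paste0("knowledge-base file not found: ", path), "herbminer_missing_file")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    kb_json_to_frame(jsonlite::fromJSON(path, simplifyDataFrame = FALSE))
  }
  build_knowledge_base(raw)
}

kb_json_to_frame <- function(entries) {
  rows <- purrr::map(entries, function(e) {
    tibble(
      canonical_name = e$canonical_name %||% NA_character_,
      pinyin         = e$pinyin %||% NA_character_,
      aliases        = paste(unlist(e$aliases), collapse = ";"),
      property       = e$property %||% NA_character_,
      tastes         = paste(unlist(e$tastes), collapse = ";"),
      meridians      = paste(unlist(e$meridians), collapse = ";"),
      category       = e$category %||% NA_character_,
      components     = paste(unlist(e$components), collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}

build_knowledge_base <- function(raw) {
  required <- c("canonical_name", "pinyin", "aliases", "property",
                "tastes", "meridians", "category")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_herbminer(
      paste0("knowledge base is missing required columns: ",
             paste(missing_cols, collapse = ", ")),
      "herbminer_malformed_kb"
    )
  }
  if (!"components" %in% names(raw)) raw$components <- NA_character_

  raw$components[is.na(raw$components)] <- ""
  is_compound <- nzchar(trimws(raw$components))
  herbs <- raw[!is_compound, , drop = FALSE]
  compounds <- raw[is_compound, , drop = FALSE]

  if (any(is.na(herbs$canonical_name) | !nzchar(trimws(herbs$canonical_name)))) {
    stop_herbminer("knowledge base has a row with an empty canonical_name",
                   "herbminer_malformed_kb")
  }

  records <- tibble(
    canonical_name = trimws(herbs$canonical_name),
    pinyin = trimws(herbs$pinyin),
    aliases = purrr::map(herbs$aliases, split_field),
    property = normalize_property(herbs$property, herbs$canonical_name),
    tastes = purrr::map(herbs$tastes, split_field),
    meridians = purrr::map(herbs$meridians, split_field),
    category = trimws(herbs$category)
  )
  validate_kb_records(records)

  alias_index <- kb_alias_index(records, compounds)

  compound_map <- list()
  if (nrow(compounds) > 0) {
    compound_map <- setNames(
      purrr::map(compounds$components, split_field),
      normalize_key(compounds$canonical_name)
    )
    known <- records$canonical_name
    for (nm in names(compound_map)) {
      unknown <- setdiff(compound_map[[nm]], known)
      if (length(unknown) > 0) {
        stop_herbminer(
          paste0("compound '", nm, "' references unknown constituent(s): ",
                 paste(unknown, collapse = ", ")),
          "herbminer_malformed_kb"
        )
      }
    }
  }

  structure(
    list(records = records, alias_index = alias_index, compound_map = compound_map),
    class = "herb_kb"
  )
}

normalize_property <- function(x, names_for_msg) {
  x <- tolower(trimws(x))
  x[x == "mild"] <- "neutral"  # common synonym on the four-natures scale
  bad <- !is.na(x) & !(x %in% herb_properties)
  if (any(bad)) {
    stop_herbminer(
      paste0("invalid property '", x[bad][1], "' for herb '",
             names_for_msg[bad][1], "' (expected one of: ",
             paste(herb_properties, collapse = ", "), ")"),
      "herbminer_malformed_kb"
    )
  }
  x
}

validate_kb_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (anyDuplicated(normalize_key(records$canonical_name))) {
    dup <- records$canonical_name[duplicated(normalize_key(records$canonical_name))][1]
    stop_herbminer(paste0("duplicate canonical_name in knowledge base: ", dup),
                   "herbminer_malformed_kb")
  }
  no_taste <- purrr::map_int(records$tastes, length) == 0
  if (any(no_taste)) {
    stop_herbminer(
      paste0("herb '", records$canonical_name[no_taste][1], "' has no tastes"),
      "herbminer_malformed_kb"
    )
  }
  bad_taste <- purrr::map_lgl(records$tastes, ~ !all(tolower(.x) %in% herb_tastes))
  if (any(bad_taste)) {
    stop_herbminer(
      paste0("herb '", records$canonical_name[bad_taste][1],
             "' has an unrecognized taste"),
      "herbminer_malformed_kb"
    )
  }
  bad_mer <- purrr::map_lgl(records$meridians, ~ !all(.x %in% herb_meridians))
  if (any(bad_mer)) {
    stop_herbminer(
      paste0("herb '", records$canonical_name[bad_mer][1],
             "' has an unrecognized meridian"),
      "herbminer_malformed_kb"
    )
  }
  bad_cat <- !is.na(records$category) & !(records$category %in% herb_categories)
  if (any(bad_cat)) {
    stop_herbminer(
      paste0("herb '", records$canonical_name[bad_cat][1],
             "' has category '", records$category[bad_cat][1],
             "', not one of the recognized action categories"),
      "herbminer_malformed_kb"
    )
  }
  invisible(records)
}

kb_alias_index <- function(records, compounds) {
  keys <- character(0)
  vals <- character(0)
  add <- function(k, v) {
    keys <<- c(keys, normalize_key(k))
    vals <<- c(vals, v)
  }
  for (i in seq_len(nrow(records))) {
    cn <- records$canonical_name[i]
    add(cn, cn)
    if (!is.na(records$pinyin[i]) && nzchar(records$pinyin[i])) add(records$pinyin[i], cn)
    for (a in records$aliases[[i]]) add(a, cn)
  }
  if (nrow(compounds) > 0) {
    for (i in seq_len(nrow(compounds))) {
      cn <- trimws(compounds$canonical_name[i])
      add(cn, cn)
      for (a in split_field(compounds$aliases[i])) add(a, cn)
    }
  }
  # the same key may legitimately repeat with the same target (e.g. pinyin
  # equal to an alias); only conflicting targets are collisions
  idx <- setNames(vals, keys)
  dup_keys <- unique(keys[duplicated(keys)])
  for (k in dup_keys) {
    claimants <- unique(vals[keys == k])
    if (length(claimants) > 1) {
      stop_herbminer(
        paste0("alias collision: '", k, "' claimed by ",
               paste(sQuote(claimants), collapse = " and ")),
        "herbminer_alias_collision"
      )
    }
  }
  idx[!duplicated(keys)]
}

#' @export
print.herb_kb <- function(x, ...) {
  cat("<herb_kb>", nrow(x$records), "herbs,",
      length(x$compound_map), "compound formulae,",
      length(x$alias_index), "lookup keys\n")
  invisible(x)
}

#' Resolve a raw herb name to its canonical name
#'
#' Looks up a raw prescription string in the knowledge base after trimming
#' whitespace and case-folding. Unknown names raise an
#' `herbminer_unknown_herb` error carrying the offending string in its
#' `raw_name` field; they are never passed through silently.
#'
#' @param raw_name Character vector of raw herb names.
#' @param kb A `herb_kb` from [read_knowledge_base()].
#' @return Character vector of canonical names.
#' @examples
#' kb <- read_knowledge_base(herbminer_example("herb_kb.csv"))
#' canonicalize(c("Huangqi", "  shanyao "), kb)
#' @export
canonicalize <- function(raw_name, kb) {
  stopifnot(inherits(kb, "herb_kb"))
  key <- normalize_key(raw_name)
  hit <- kb$alias_index[key]
  if (anyNA(hit)) {
    bad <- raw_name[is.na(hit)][1]
    stop_herbminer(paste0("unknown herb name: '", bad, "'"),
                   "herbminer_unknown_herb", raw_name = bad)
  }
  unname(hit)
}

#' Decompose a compound formula into constituent herbs
#'
#' If `raw_name` resolves to a registered compound formula, returns its
#' constituent canonical herbs in knowledge-base order; otherwise returns the
#' singleton [canonicalize()] result.
#'
#' @inheritParams canonicalize
#' @param raw_name A single raw name (herb or compound formula).
#' @return Character vector of canonical herb names.
#' @export
decompose_compound <- function(raw_name, kb) {
  stopifnot(inherits(kb, "herb_kb"), length(raw_name) == 1)
  key <- normalize_key(canonicalize(raw_name, kb))
  if (key %in% names(kb$compound_map)) {
    kb$compound_map[[key]]
  } else {
    canonicalize(raw_name, kb)
  }
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
herbminer_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "herbminer"))
  } else {
    path <- system.file("extdata", file, package = "herbminer")
    if (!nzchar(path)) stop_herbminer(paste0("no bundled file: ", file),
                                      "herbminer_missing_file")
    path
  }
}
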