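# Fixtures are built in code at test time.

bundled_kb <- function() read_knowledge_base(herbminer_example("herb_kb.csv"))

# write a minimal KB csv and return its path
write_mini_kb <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "canonical_name,pinyin,aliases,property,tastes,meridians,category,components"
  writeLines(c(header, rows), path)
  path
}

mini_kb <- function() {
  path <- write_mini_kb(c(
    "Radix Astragali,Huangqi,Astragali Radix,warm,sweet,Spleen;Lung,deficiency-tonifying,",
    "Rhizoma Dioscoreae,Shanyao,,neutral,sweet,Spleen;Lung;Kidney,deficiency-tonifying,",
    "Poria,Fuling,Fulin,neutral,sweet;bland,Heart;Spleen;Kidney,dampness-draining diuretic,",
    "TestFormulaAB,,,,,,,Radix Astragali;Rhizoma Dioscoreae"
  ))
  read_knowledge_base(path)
}

# transaction_db from a list of character baskets
db_from_baskets <- function(baskets, ids = NULL) {
  ids <- ids %||% sprintf("t%03d", seq_along(baskets))
  items <- sort(unique(unlist(baskets)))
  inc <- matrix(FALSE, nrow = length(items), ncol = length(baskets),
                dimnames = list(items, ids))
  for (j in seq_along(baskets)) inc[unique(baskets[[j]]), j] <- TRUE
  transaction_db(inc)
}

# random small database for property-style tests
random_db <- function(n_items, n_trans, p = 0.4) {
  items <- sprintf("I%02d", seq_len(n_items))
  inc <- matrix(stats::runif(n_items * n_trans) < p, nrow = n_items,
                dimnames = list(items, sprintf("t%03d", seq_len(n_trans))))
  # every transaction keeps at least the possibility of being empty; that is fine
  transaction_db(inc)
}

itemset_keys <- function(itemsets) {
  vapply(itemsets$items, paste, character(1), collapse = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# fixed grid of marginal probabilities below the sqrt of the support threshold
runif_fixed <- function(k) seq(0.2, 0.45, length.out = k)
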