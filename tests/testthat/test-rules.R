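test_that("level-wise search matches brute-force enumeration on a worked example", {
  db <- db_from_baskets(list(c("A", "B"), c("A", "B"), c("A", "C"), "A"))
  its <- frequent_itemsets(db, 0.5)
  keys <- itemset_keys(its)
  expect_setequal(keys, c("A", "B", "A|B"))
  expect_equal(its$count[keys == "A"], 4L)
  expect_equal(its$count[keys == "A|B"], 2L)
  # {C} has support 1/4 < 0.5 and is excluded
  expect_false("C" %in% keys)
  bf <- brute_force_frequent(db, 0.5)
  expect_equal(its[c("items", "size", "count")], bf[c("items", "size", "count")])
})

test_that("no herb is universal implies no itemsets at support 1", {
  db <- db_from_baskets(list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(nrow(frequent_itemsets(db, 1.0)), 0)
})

test_that("level-wise and brute-force searches agree on random databases", {
  set.seed(101)
  for (rep in 1:60) {
    db <- random_db(n_items = sample(3:10, 1), n_trans = sample(5:30, 1),
                    p = runif(1, 0.2, 0.8))
    minsup <- runif(1, 0.1, 0.7)
    a <- frequent_itemsets(db, minsup)
    b <- brute_force_frequent(db, minsup)
    expect_equal(itemset_keys(a), itemset_keys(b))
    expect_equal(a$count, b$count)
  }
})

test_that("emitted itemsets satisfy anti-monotonicity", {
  set.seed(5)
  db <- random_db(n_items = 9, n_trans = 40, p = 0.5)
  its <- frequent_itemsets(db, 0.25)
  keys <- itemset_keys(its)
  counts <- setNames(its$count, keys)
  for (i in which(its$size >= 2)) {
    s <- its$items[[i]]
    for (drop in seq_along(s)) {
      sub <- paste(s[-drop], collapse = "|")
      expect_true(sub %in% keys)
      expect_lte(its$count[i], counts[[sub]])
    }
  }
})

test_that("rule metrics reproduce reconstructed herb-pair values", {
  # counts reconstructed from printed marginals and supports
  m1 <- rule_metrics(154, 174, 231, 299)
  expect_equal(m1$support_pct, 51.51)
  expect_equal(m1$confidence_pct, 88.51)
  expect_equal(m1$lift, 1.15)
  m2 <- rule_metrics(134, 140, 231, 299)
  expect_equal(m2$support_pct, 44.82)
  expect_equal(m2$confidence_pct, 95.71)
  expect_equal(m2$lift, 1.24)
  # universal consequent: confidence 100, lift 1
  m3 <- rule_metrics(10, 10, 20, 20)
  expect_equal(m3$confidence_pct, 100.00)
  expect_equal(m3$lift, 1.00)
})

test_that("rule metric preconditions are enforced", {
  expect_error(rule_metrics(10, 5, 20, 30), class = "herbminer_bad_counts")
  expect_error(rule_metrics(1, 0, 5, 10), class = "herbminer_bad_counts")
  expect_error(rule_metrics(1, 5, 40, 30), class = "herbminer_bad_counts")
})

test_that("rule generation emits the reconstructed herb pair at the standard thresholds", {
  db <- build_exact_fixture(
    299,
    c("Rhizoma Dioscoreae" = 231, "Radix Astragali" = 174),
    list(list("Rhizoma Dioscoreae", "Radix Astragali", 154))
  )
  its <- frequent_itemsets(db, 0.30)
  expect_true("Radix Astragali|Rhizoma Dioscoreae" %in% itemset_keys(its))
  rules <- generate_rules(its, db, 0.85)
  expect_equal(nrow(rules), 1)
  expect_equal(rules$lhs_label, "Radix Astragali")
  expect_equal(rules$rhs_label, "Rhizoma Dioscoreae")
  expect_equal(rules$support_pct, 51.51)
  expect_equal(rules$confidence_pct, 88.51)
  expect_equal(rules$lift, 1.15)
  # the reverse direction has confidence 154/231 = 66.7% and is not emitted
  expect_false(any(rules$lhs_label == "Rhizoma Dioscoreae"))
})

test_that("perfect confidence threshold excludes imperfect implications", {
  # A => B holds in 2 of 3 A-transactions and B => A in 2 of 2; only the
  # latter survives confidence 1.0
  db <- db_from_baskets(list(c("A", "B"), c("A", "B"), c("A")))
  its <- frequent_itemsets(db, 0.5)
  perfect <- generate_rules(its, db, 1.0)
  expect_equal(perfect$lhs_label, "B")
  # with an imperfect implication in both directions nothing survives
  db2 <- db_from_baskets(list(c("A", "B"), c("A"), c("B")))
  its2 <- frequent_itemsets(db2, 0.3)
  expect_equal(nrow(generate_rules(its2, db2, 1.0)), 0)
})

test_that("max_rhs bounds the consequent partitions considered", {
  db <- db_from_baskets(rep(list(c("A", "B", "C")), 4))
  its <- frequent_itemsets(db, 0.9)
  r1 <- generate_rules(its, db, 0.5, max_rhs = 1)
  expect_equal(sum(lengths(r1$lhs) == 2), 3)  # {A,B,C} contributes 3 single-RHS rules
  r2 <- generate_rules(its, db, 0.5, max_rhs = 2)
  expect_equal(sum(lengths(r2$rhs) == 2), 3)  # only {A,B,C} can donate a 2-item RHS
})

test_that("rule-set structural identities hold on mined databases", {
  set.seed(77)
  db <- random_db(n_items = 8, n_trans = 40, p = 0.55)
  its <- frequent_itemsets(db, 0.2)
  rules <- generate_rules(its, db, 0.4)
  n <- n_transactions(db)
  ic <- setNames(item_counts(db)$count, item_counts(db)$herb)
  for (i in seq_len(nrow(rules))) {
    expect_length(intersect(rules$lhs[[i]], rules$rhs[[i]]), 0)
    expect_lte(rules$support_pct[i], rules$confidence_pct[i] + 1e-9)
    # lift x consequent frequency = confidence at the rounded scale
    c_y <- ic[rules$rhs[[i]]]
    recomputed <- round_half_up((rules$confidence_pct[i] / 100) / (c_y / n), 2)
    expect_lt(abs(recomputed - rules$lift[i]), 0.02)
  }
  # monotone filtering: tighter thresholds never add rules
  tighter <- generate_rules(frequent_itemsets(db, 0.3), db, 0.5)
  key <- function(r) paste(r$lhs_label, r$rhs_label)
  expect_true(all(key(tighter) %in% key(rules)))
})

test_that("brute force refuses oversized universes and degenerate support", {
  db <- random_db(n_items = 21, n_trans = 5)
  expect_error(brute_force_frequent(db, 0.5),
               class = "herbminer_universe_too_large")
  small <- random_db(n_items = 3, n_trans = 5)
  expect_error(brute_force_frequent(small, 0), class = "herbminer_bad_threshold")
  expect_error(frequent_itemsets(small, 0), class = "herbminer_bad_threshold")
})

test_that("consistency report flags reported rows irreproducible under the metric definitions", {
  reported <- tibble::tibble(
    lhs_label = c("Radix Astragali", "Poria"),
    rhs_label = c("Rhizoma Dioscoreae", "Rhizoma Dioscoreae"),
    support_pct = c(51.51, 47.16),
    confidence_pct = c(88.51, 85.45),
    lift = c(1.15, 1.11)
  )
  marginals <- tibble::tibble(
    herb = c("Radix Astragali", "Poria", "Rhizoma Dioscoreae"),
    count = c(174L, 166L, 231L)
  )
  rep <- rule_consistency_report(reported, marginals, n = 299)
  expect_true(rep$confidence_consistent[1])   # 154/174 reproduces 88.51
  expect_false(rep$confidence_consistent[2])  # 141/166 = 84.94, not 85.45
  expect_equal(rep$implied_joint, c(154L, 141L))
})
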