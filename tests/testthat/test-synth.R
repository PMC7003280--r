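test_that("independence generator respects degenerate marginals and the seed contract", {
  cfg <- synth_config(50, marginals = c(Always = 1, Never = 0, Half = 0.5), seed = 9)
  db <- generate_independent(cfg)
  expect_equal(n_transactions(db), 50)
  expect_true(all(db$incidence["Always", ]))
  expect_false(any(db$incidence["Never", ]))
  # same seed, bit-identical; different seed differs
  db2 <- generate_independent(cfg)
  expect_identical(db$incidence, db2$incidence)
  cfg3 <- synth_config(50, marginals = c(Always = 1, Never = 0, Half = 0.5), seed = 10)
  expect_false(identical(db$incidence, generate_independent(cfg3)$incidence))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_independent(synth_config(10, marginals = c(A = 0.5), seed = 2)))
  expect_identical(runif(1), before)
})

test_that("independent marginals are recovered within binomial error at large n", {
  cfg <- synth_config(5000, marginals = c(Common = 0.773), seed = 21)
  db <- generate_independent(cfg)
  phat <- mean(db$incidence["Common", ])
  se3 <- 3 * sqrt(0.773 * (1 - 0.773) / 5000)
  expect_lt(abs(phat - 0.773), se3)
})

test_that("a deterministic template reproduces itself; mixtures plant lift structure", {
  one <- synth_config(20, templates = list(c(A = 1, B = 1)), seed = 5)
  db <- generate_template_mixture(one)$db
  expect_true(all(db$incidence))
  # two disjoint templates: within-template lift > 1, between < 1
  cfg <- synth_config(
    1500,
    templates = list(c(A1 = 0.9, A2 = 0.9), c(B1 = 0.9, B2 = 0.9)),
    seed = 33
  )
  gen <- generate_template_mixture(cfg)
  ic <- setNames(item_counts(gen$db)$count, item_counts(gen$db)$herb)
  pc <- pair_counts(gen$db)
  n <- n_transactions(gen$db)
  lift_of <- function(a, b) {
    row <- pc[pc$herb_a == min(a, b) & pc$herb_b == max(a, b), ]
    joint <- if (nrow(row) == 0) 0 else row$count
    (joint / n) / ((ic[a] / n) * (ic[b] / n))
  }
  expect_gt(lift_of("A1", "A2"), 1)
  expect_gt(lift_of("B1", "B2"), 1)
  expect_lt(lift_of("A1", "B1"), 1)
  # planted truth bookkeeping is consistent with the generated data
  expect_equal(nrow(gen$truth$template_of), n)
  expect_length(gen$truth$core_herbs, 0)
  expect_setequal(gen$truth$template_herbs[[1]], c("A1", "A2"))
})

test_that("exact fixtures realize marginal and pair constraints exactly", {
  db <- build_exact_fixture(
    299,
    c("Rhizoma Dioscoreae" = 231, "Radix Astragali" = 174, "Fructus Corni" = 140),
    list(list("Rhizoma Dioscoreae", "Radix Astragali", 154),
         list("Rhizoma Dioscoreae", "Fructus Corni", 134))
  )
  ic <- setNames(item_counts(db)$count, item_counts(db)$herb)
  expect_equal(ic[["Rhizoma Dioscoreae"]], 231L)
  expect_equal(ic[["Radix Astragali"]], 174L)
  pc <- pair_counts(db)
  expect_equal(pc$count[pc$herb_a == "Radix Astragali" &
                          pc$herb_b == "Rhizoma Dioscoreae"], 154L)
  expect_equal(pc$count[pc$herb_a == "Fructus Corni" &
                          pc$herb_b == "Rhizoma Dioscoreae"], 134L)
})

test_that("fixture construction is exact across random feasible tree constraints", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(20:80, 1)
    herbs <- sprintf("H%02d", 1:6)
    counts <- setNames(sample(1:n, 6, replace = TRUE), herbs)
    # random tree over the herbs; overlaps drawn within the Frechet bounds
    cons <- list()
    for (i in 2:6) {
      parent <- herbs[sample(i - 1, 1)]
      lo <- max(0, counts[herbs[i]] + counts[parent] - n)
      hi <- min(counts[herbs[i]], counts[parent])
      overlap <- lo + sample.int(hi - lo + 1, 1) - 1
      cons[[length(cons) + 1]] <- list(parent, herbs[i], overlap)
    }
    db <- build_exact_fixture(n, counts, cons)
    ic <- setNames(item_counts(db)$count, item_counts(db)$herb)
    expect_equal(ic[herbs], counts)
    pc <- pair_counts(db)
    for (cn in cons) {
      a <- min(cn[[1]], cn[[2]]); b <- max(cn[[1]], cn[[2]])
      hit <- pc$count[pc$herb_a == a & pc$herb_b == b]
      expect_equal(if (length(hit) == 0) 0L else hit, as.integer(cn[[3]]))
    }
  }
})

test_that("infeasible or cyclic constraints are rejected with informative errors", {
  expect_error(
    build_exact_fixture(10, c(A = 3, B = 4), list(list("A", "B", 5))),
    class = "herbminer_infeasible"
  )
  expect_error(
    build_exact_fixture(10, c(A = 9, B = 9), list(list("A", "B", 5))),
    class = "herbminer_infeasible"
  )
  expect_error(
    build_exact_fixture(10, c(A = 5, B = 5, C = 5),
                        list(list("A", "B", 3), list("B", "C", 3),
                             list("A", "C", 3))),
    class = "herbminer_constraint_topology"
  )
  expect_error(
    build_exact_fixture(10, c(A = 5), list(list("A", "A", 2))),
    class = "herbminer_infeasible"
  )
})

test_that("independence-model data produce no rules beyond what marginals imply", {
  # all pairwise expected supports (<= 0.45^2 ~ 0.2) sit far below 0.30
  cfg <- synth_config(
    400, marginals = setNames(runif_fixed(10), sprintf("M%02d", 1:10)), seed = 61
  )
  db <- generate_independent(cfg)
  its <- frequent_itemsets(db, 0.30)
  expect_true(all(its$size == 1))
  expect_equal(nrow(generate_rules(its, db, 0.85)), 0)
})
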