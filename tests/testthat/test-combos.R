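test_that("exact counts assign each window to exactly one key", {
  expo <- exposures_from_windows(list(c("A", "B"), "A", c("A", "B")))
  exact <- exact_combo_counts(expo)
  expect_identical(exact[key == "A|B"]$count, 2L)
  expect_identical(exact[key == "A"]$count, 1L)
  expect_identical(attr(exact, "W_exposed"), 3L)
  expect_identical(sum(exact$count), 3L)

  empty <- exact_combo_counts(data.table(patient_id = character(),
                                         window_index = integer(),
                                         ingredient = character()))
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "W_exposed"), 0L)

  one <- exact_combo_counts(exposures_from_windows(list(c("A", "B", "C"))))
  expect_identical(one$key, "A|B|C")
  expect_identical(one$count, 1L)
})

test_that("a single A+B+C window answers 1 to all seven subset queries", {
  exact <- exact_combo_counts(exposures_from_windows(list(c("A", "B", "C"))))
  idx <- combo_index(exact)
  for (q in all_subsets(c("A", "B", "C")))
    expect_identical(atleast_count(q, exact, idx), 1L)
  expect_identical(atleast_count("Z", exact, idx), 0L)
})

test_that("at-least counts are superset sums over the exact table", {
  expo <- exposures_from_windows(list(c("A", "B"), c("A", "B"), "A"))
  exact <- exact_combo_counts(expo)
  expect_identical(atleast_count("A", exact), 3L)
  expect_identical(atleast_count(c("A", "B"), exact), 2L)
  expect_identical(atleast_count("A|B", exact), 2L)  # key-string form
})

test_that("index-based at-least equals the naive superset sum on random data", {
  for (seed in 1:4) {
    claims <- random_claims(250L, n_drugs = 7L, seed = seed)
    expo <- build_exposure_table(claims, 30L)$exposures
    exact <- exact_combo_counts(expo)
    idx <- combo_index(exact)
    drugs <- sort(unique(expo$ingredient))
    for (q in all_subsets(drugs, 3L)) {
      expect_identical(atleast_count(q, exact, idx),
                       atleast_count_naive(q, exact),
                       info = paste("seed", seed, "query", q))
    }
  }
})

test_that("a k-drug window contributes to exactly 2^k - 1 at-least keys", {
  for (k in 2:5) {
    items <- paste0("g", seq_len(k))
    exact <- exact_combo_counts(exposures_from_windows(list(items)))
    idx <- combo_index(exact)
    hits <- vapply(all_subsets(items), atleast_count, integer(1),
                   exact = exact, index = idx)
    expect_identical(sum(hits > 0L), as.integer(2^k - 1))
    expect_true(all(hits[hits > 0L] == 1L))
  }
})

test_that("Apriori candidate generation joins and prunes correctly", {
  singles <- c(A = 1500L, B = 1200L, C = 1100L, D = 10L)
  expect_identical(generate_candidates(2, singles, 1000L),
                   c("A|B", "A|C", "B|C"))
  # ABC requires all three pairs to qualify; BC is below threshold
  pairs <- c("A|B" = 1500L, "A|C" = 1200L, "B|C" = 900L)
  expect_identical(generate_candidates(3, pairs, 1000L), character())
  pairs["B|C"] <- 1000L
  expect_identical(generate_candidates(3, pairs, 1000L), "A|B|C")
  expect_error(generate_candidates(1, singles), "n must be")
  expect_error(generate_candidates(6, singles), "n must be")
  expect_identical(generate_candidates(6, singles, max_n = 6L), character())
})

test_that("threshold 0 enumerates all combinations of observed drugs", {
  expo <- exposures_from_windows(list(c("A", "B"), c("B", "C"), "C"))
  exact <- exact_combo_counts(expo)
  lv <- count_combos(exact, max_n = 3L, support_threshold = 0L)
  expect_identical(
    generate_candidates(2, lv[["1"]], 0L),
    c("A|B", "A|C", "B|C"))
  expect_error(generate_candidates(3, lv[["1"]], 0L), "size")
})

test_that("count_combos finds every frequent combo on random cohorts", {
  for (seed in 1:3) {
    claims <- random_claims(300L, n_drugs = 6L, seed = seed + 10L)
    expo <- build_exposure_table(claims, 30L)$exposures
    exact <- exact_combo_counts(expo)
    lv <- count_combos(exact, max_n = 4L, support_threshold = 3L)
    drugs <- sort(unique(expo$ingredient))
    for (k in 2:4) {
      truth <- Filter(function(q) atleast_count_naive(q, exact) >= 3L,
                      utils::combn(drugs, k, paste, collapse = "|"))
      expect_true(all(truth %in% lv[[as.character(k)]]$key),
                  info = paste("seed", seed, "k", k))
      # and the reported counts are right
      got <- lv[[as.character(k)]]
      expect_identical(got$atleast_exposure_count,
                       vapply(got$key, atleast_count_naive, integer(1),
                              exact = exact, USE.NAMES = FALSE))
    }
  }
})

test_that("class translation deduplicates within window and drops unclassified", {
  tm <- toy_mapping()
  expo <- exposures_from_windows(list(c("A", "B", "C")))
  cls <- class_exposures(expo, tm)
  expect_identical(cls$exposures$ingredient, c("Q01", "R01"))
  expect_identical(cls$n_dropped, 0L)

  # an ingredient without an ATC code is dropped with a tally
  m2 <- drug_mapping(
    list(A = "A", Zz = "Zz"),
    data.frame(ingredient = c("A", "Zz"), rxcui = c("1", "2"),
               umls_cui = c("C1", "C2"), drugbank_id = c("D1", "D2"),
               atc_code = c("Q01AA01", NA), atc_name = c("Q", NA)))
  cls2 <- class_exposures(exposures_from_windows(list(c("A", "Zz"))), m2)
  expect_identical(cls2$exposures$ingredient, "Q01")
  expect_identical(cls2$n_dropped, 1L)
})

test_that("class-level at-least counts dominate distinct-class ingredient queries", {
  # coarsening can only merge windows: querying {Q01, R01} at class level
  # counts at least as many windows as {A, C} at ingredient level
  expo <- exposures_from_windows(list(c("A", "C"), c("B", "C"), "A"))
  exact_ing <- exact_combo_counts(expo)
  cls <- class_exposures(expo, toy_mapping())$exposures
  exact_cls <- exact_combo_counts(cls)
  expect_gte(atleast_count(c("Q01", "R01"), exact_cls),
             atleast_count(c("A", "C"), exact_ing))
})
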