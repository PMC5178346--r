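test_that("the three accumulation strategies deduplicate as documented", {
  # two records of C1 share the exact same isolation source
  ev <- dplyr::bind_rows(
    ev_row("C1", "r1", "lake sediment", "10", c("E:3" = 1)),
    ev_row("C1", "r2", "lake sediment", "10", c("E:3" = 1))
  )
  expect_equal(accumulate_counts(ev, "flat")$count, 2L)
  expect_equal(accumulate_counts(ev, "unique_isolation")$count, 1L)
  expect_equal(accumulate_counts(ev, "unique_pubmed_unique_isolation")$count, 1L)

  # same texts but distinct pubmed ids: the pair key keeps both
  ev2 <- dplyr::bind_rows(
    ev_row("C1", "r1", "lake sediment", "10", c("E:3" = 1)),
    ev_row("C1", "r2", "lake sediment", "20", c("E:3" = 1))
  )
  expect_equal(accumulate_counts(ev2, "unique_pubmed_unique_isolation")$count, 2L)
  expect_equal(accumulate_counts(ev2, "unique_isolation")$count, 1L)

  # a single evidence row is invariant across strategies
  ev3 <- ev_row("C1", "r1", "soil", "1", c("E:5" = 1))
  for (s in c("flat", "unique_isolation", "unique_pubmed_unique_isolation")) {
    expect_equal(accumulate_counts(ev3, s)$count, 1L, info = s)
  }
  expect_error(accumulate_counts(ev3, "bogus"), class = "envotag_argument_error")
  expect_equal(nrow(accumulate_counts(ev3[0, ], "flat")), 0)
})

test_that("dedup keys are per-query, case-sensitive, and trim outer whitespace", {
  ev <- dplyr::bind_rows(
    ev_row("C1", "r1", "Lake sediment", NA_character_, c("E:3" = 1)),
    ev_row("C1", "r2", "lake sediment", NA_character_, c("E:3" = 1)),
    ev_row("C1", "r3", " lake sediment ", NA_character_, c("E:3" = 1)),
    ev_row("C2", "r4", "lake sediment", NA_character_, c("E:3" = 1))
  )
  ui <- accumulate_counts(ev, "unique_isolation")
  expect_equal(ui$count[ui$query_id == "C1"], 2L)  # case differs; whitespace merges
  expect_equal(ui$count[ui$query_id == "C2"], 1L)  # other query unaffected
  # missing pubmed ids act as one explicit "absent" key
  up <- accumulate_counts(ev, "unique_pubmed_unique_isolation")
  expect_equal(up$count[up$query_id == "C1"], 2L)
})

test_that("unique_isolation counts never exceed flat counts element-wise", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      ev <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        ev_row(sample(c("C1", "C2"), 1), paste0("r", i),
               sample(c("soil", "fresh water", "sea water"), 1),
               sample(c("1", "2", NA), 1),
               stats::setNames(sample(1:2, 1), sample(c("E:3", "E:4", "E:5"), 1)))
      }))
      flat <- accumulate_counts(ev, "flat")
      ui <- accumulate_counts(ev, "unique_isolation")
      joined <- dplyr::left_join(ui, flat, by = c("query_id", "term_id"),
                                 suffix = c("_ui", "_flat"))
      expect_true(all(joined$count_ui <= joined$count_flat))
      # all three coincide when all sources within a query are distinct
      dedup <- dplyr::distinct(ev, query_id, isolation_source, .keep_all = TRUE)
      expect_equal(accumulate_counts(dedup, "unique_isolation"),
                   accumulate_counts(dedup, "flat"))
    }
  })
})

test_that("backtracking propagates counts with hand-checked expectations", {
  counts <- tibble::tibble(term_id = c("E:3", "E:5"), count = c(1, 1))
  bt <- backtrack(counts, mini_ont)
  expect_equal(stats::setNames(bt$count, bt$term_id),
               c("E:1" = 2, "E:2" = 1, "E:3" = 1, "E:5" = 1))

  root_only <- tibble::tibble(term_id = "E:1", count = 4)
  expect_equal(backtrack(root_only, mini_ont), root_only)

  # diamond: W gains exactly +1, not one per path
  d <- backtrack(tibble::tibble(term_id = "D:X", count = 1), diamond_ont)
  expect_equal(stats::setNames(d$count, d$term_id),
               c("D:W" = 1, "D:X" = 1, "D:Y" = 1, "D:Z" = 1))

  expect_error(backtrack(tibble::tibble(term_id = "NOPE", count = 1), mini_ont),
               "NOPE", class = "envotag_lookup_error")
})

test_that("backtracking agrees with the transitive-closure oracle on random DAGs", {
  withr::with_seed(13, {
    for (rep in 1:8) {
      dag <- random_dag(sample(5:50, 1), stats::runif(1, 0.05, 0.25))
      picked <- sample(dag$ids, min(5, length(dag$ids)))
      counts <- tibble::tibble(term_id = picked,
                               count = sample(1:5, length(picked), replace = TRUE))
      got <- backtrack(counts, dag$ont)
      expect_equal(got$count, oracle_backtrack(counts, dag$edges)$count)
      expect_equal(got$term_id, oracle_backtrack(counts, dag$edges)$term_id)
      # counts never decrease
      joined <- dplyr::left_join(counts, got, by = "term_id", suffix = c("", "_bt"))
      expect_true(all(joined$count_bt >= joined$count))
      expect_gte(sum(got$count), sum(counts$count))
    }
  })
})

test_that("on a tree the root accumulates the total tag count", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      tr <- random_tree(sample(5:30, 1))
      picked <- sample(tr$ids, min(6, length(tr$ids)))
      counts <- tibble::tibble(term_id = picked,
                               count = sample(1:4, length(picked), replace = TRUE))
      bt <- backtrack(counts, tr$ont)
      expect_equal(bt$count[bt$term_id == "T1"], sum(counts$count))
    }
  })
})

test_that("restriction drops exactly the terms outside the subtree", {
  counts <- tibble::tibble(term_id = c("E:3", "E:5"), count = c(2, 1))
  r <- apply_restriction(counts, mini_ont, "E:2")
  expect_equal(r$term_id, "E:3")
  expect_equal(r$count, 2)
  expect_equal(apply_restriction(counts, mini_ont, "E:1"), counts)
  expect_equal(nrow(apply_restriction(counts[counts$term_id == "E:5", ],
                                      mini_ont, "E:2")), 0)
  expect_error(apply_restriction(counts, mini_ont, "NOPE"),
               class = "envotag_lookup_error")
})

test_that("row normalization yields compositions with zero rows preserved", {
  raw <- tibble::tibble(query_id = c("C1", "C1", "C2"),
                        term_id = c("E:3", "E:5", "E:4"),
                        count = c(1, 1, 3))
  S <- normalize_rows(raw, sequence_ids = c("C1", "C2", "C3"))
  expect_equal(unname(S["C1", c("E:3", "E:5")]), c(0.5, 0.5))
  expect_equal(unname(S["C2", "E:4"]), 1)
  expect_equal(sum(S["C3", ]), 0)
  expect_equal(attr(S, "unannotated"), "C3")
  expect_error(normalize_rows(dplyr::mutate(raw, count = -count)),
               class = "envotag_validation_error")
})

test_that("sample matrix matches hand examples and the double-loop oracle", {
  S <- normalize_rows(tibble::tibble(query_id = c("C1", "C2"),
                                     term_id = c("E:3", "E:5"),
                                     count = c(2, 5)))
  f_even <- matrix(c(2, 2), nrow = 1, dimnames = list("Z", c("C1", "C2")))
  expect_equal(unname(sample_matrix(f_even, S)["Z", ]), c(0.5, 0.5))
  f_skew <- matrix(c(1, 3), nrow = 1, dimnames = list("Z", c("C1", "C2")))
  expect_equal(unname(sample_matrix(f_skew, S)["Z", ]), c(0.25, 0.75))

  expect_error(sample_matrix(
    matrix(1, 1, 1, dimnames = list("Z", "C9")), S), "C9",
    class = "envotag_input_error")

  withr::with_seed(23, {
    for (rep in 1:10) {
      # 5 samples x 4 sequences x 6 terms
      raw <- tidyr::expand_grid(query_id = paste0("C", 1:4),
                                term_id = paste0("E:", 1:6)) |>
        dplyr::mutate(count = sample(0:5, 24, replace = TRUE))
      S <- normalize_rows(raw[raw$count > 0, ], sequence_ids = paste0("C", 1:4))
      f <- matrix(sample(0:10, 20, replace = TRUE), nrow = 5,
                  dimnames = list(paste0("s", 1:5), paste0("C", 1:4)))
      N <- suppressWarnings(sample_matrix(f, S))
      oracle <- oracle_sample_matrix(f, S)
      expect_equal(dimnames(N), dimnames(oracle))
      expect_equal(as.vector(N), as.vector(oracle), tolerance = 1e-12)
    }
  })
})

test_that("zero-frequency samples keep a zero row with a warning", {
  S <- normalize_rows(tibble::tibble(query_id = "C1", term_id = "E:3", count = 1))
  f <- matrix(c(3, 0), nrow = 2, dimnames = list(c("a", "b"), "C1"))
  expect_warning(N <- sample_matrix(f, S), "zero")
  expect_equal(sum(N["b", ]), 0)
  expect_equal(sum(N["a", ]), 1)
})
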