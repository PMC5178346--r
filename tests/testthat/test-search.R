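make_hit <- function(query_id = "C1", subject_id = "gi|1|gb|X1.1|",
                     pct_identity = 99, aln_length = 100, evalue = 1e-30,
                     bitscore = 200, query_length = 100) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 pct_identity = pct_identity, aln_length = aln_length,
                 mismatch = 0, gapopen = 0, qstart = 1, qend = aln_length,
                 sstart = 1, send = aln_length, evalue = evalue,
                 bitscore = bitscore, query_length = query_length)
}

test_that("tabular results parse with query lengths joined", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("C1\tgi|1|gb|A.1|\t99.0\t100\t1\t0\t1\t100\t5\t104\t1e-30\t180",
               "C1\tAB1.1\t98.0\t99\t2\t0\t1\t99\t5\t103\t1e-20\t160",
               "C2\tAB2.1\t97.5\t150\t3\t1\t1\t150\t9\t158\t1e-10\t140"), f)
  hits <- parse_tabular(f, c(C1 = 100, C2 = 150))
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_length, c(100, 100, 150))

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(parse_tabular(empty, c(C1 = 100))), 0)
})

test_that("tabular validation rejects impossible values and short rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines("C1\tA.1\t101.0\t100\t1\t0\t1\t100\t5\t104\t1e-30\t180", f)
  expect_error(parse_tabular(f, c(C1 = 100)), class = "envotag_validation_error")

  f2 <- tempfile(fileext = ".tsv")
  writeLines("C1\tA.1\t99.0", f2)
  expect_error(parse_tabular(f2, c(C1 = 100)), class = "envotag_parse_error")

  f3 <- tempfile(fileext = ".tsv")
  writeLines("C9\tA.1\t99.0\t100\t1\t0\t1\t100\t5\t104\t1e-30\t180", f3)
  expect_error(parse_tabular(f3, c(C1 = 100)), "C9", class = "envotag_input_error")
})

test_that("threshold screen keeps and drops hits per the defaults", {
  keep <- make_hit(evalue = 1e-5, pct_identity = 98, aln_length = 99,
                   query_length = 100)
  expect_equal(nrow(filter_hits(keep)), 1)

  drop_e <- make_hit(evalue = 1e-2, pct_identity = 99, aln_length = 100)
  expect_equal(nrow(filter_hits(drop_e)), 0)
  drop_cov <- make_hit(aln_length = 80, query_length = 100)
  expect_equal(nrow(filter_hits(drop_cov)), 0)
  drop_id <- make_hit(pct_identity = 95)
  expect_equal(nrow(filter_hits(drop_id)), 0)
})

test_that("max_targets keeps the 10 smallest e-values (brute-force oracle)", {
  hits <- dplyr::bind_rows(lapply(1:12, function(k) {
    make_hit(subject_id = sprintf("AB%02d.1", k), evalue = k * 1e-20,
             bitscore = 300 - k)
  }))
  ht <- filter_hits(hits)
  expect_equal(nrow(ht), 10)
  oracle <- hits$subject_id[order(hits$evalue)][1:10]
  expect_setequal(ht$subject_id, oracle)
})

test_that("ranking ties break by bitscore then subject id; duplicates collapse", {
  hits <- dplyr::bind_rows(
    make_hit(subject_id = "B.1", evalue = 1e-20, bitscore = 100),
    make_hit(subject_id = "A.1", evalue = 1e-20, bitscore = 200),
    make_hit(subject_id = "C.1", evalue = 1e-20, bitscore = 100),
    make_hit(subject_id = "A.1", evalue = 1e-25, bitscore = 210)
  )
  ht <- filter_hits(hits)
  expect_equal(ht$subject_id, c("A.1", "B.1", "C.1"))  # A by evalue, then ties
  expect_equal(sum(ht$subject_id == "A.1"), 1)
})

test_that("filter_hits is idempotent and monotone in its thresholds", {
  withr::with_seed(3, {
    hits <- dplyr::bind_rows(lapply(1:30, function(k) {
      make_hit(query_id = sample(c("C1", "C2"), 1),
               subject_id = sprintf("S%02d.1", k),
               pct_identity = stats::runif(1, 90, 100),
               aln_length = sample(80:100, 1),
               evalue = 10^stats::runif(1, -40, -2),
               bitscore = stats::runif(1, 50, 300))
    }))
  })
  strict <- filter_hits(hits)
  # idempotence: re-filtering the retained rows changes nothing
  again <- filter_hits(
    dplyr::semi_join(hits, strict, by = c("query_id", "subject_id")))
  expect_equal(again$subject_id, strict$subject_id)
  # loosening every threshold never shrinks the retained set
  loose <- filter_hits(hits, filter_params(1e-2, 0.8, 0.9, 30))
  expect_true(all(paste(strict$query_id, strict$subject_id) %in%
                    paste(loose$query_id, loose$subject_id)))
  expect_true(all(table(strict$query_id) <= 10))
})

test_that("record ids come from the gi dialect or pass through", {
  expect_equal(extract_record_id("gi|123456|gb|AY123456.1|"), "123456")
  expect_equal(extract_record_id("AY123456.1"), "AY123456.1")
  expect_error(extract_record_id(""), class = "envotag_argument_error")
})

test_that("default parameters match the documented screen", {
  p <- filter_params()
  expect_equal(p$max_evalue, 1e-4)
  expect_equal(p$min_coverage, 0.97)
  expect_equal(p$min_identity, 0.97)
  expect_equal(p$max_targets, 10L)
})
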