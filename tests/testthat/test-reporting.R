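toy_S <- normalize_rows(
  tibble::tibble(query_id = c("C1", "C1", "C2"),
                 term_id = c("E:3", "E:5", "E:4"),
                 count = c(1, 1, 3)),
  sequence_ids = c("C1", "C2")
)

test_that("sequence-term TSV has terms as rows and sequences as columns", {
  out <- tempfile(fileext = ".tsv")
  name_map <- tibble::tibble(new_id = c("C1", "C2"),
                             original_id = c("OTU_7", "OTU_2"))
  write_seq_term_tsv(toy_S, out, ont = mini_ont, name_map = name_map)
  lines <- readLines(out)
  expect_length(lines, 4)  # header + 3 term rows
  expect_equal(strsplit(lines[1], "\t")[[1]], c("term_id", "term_name", "OTU_7", "OTU_2"))
  # zero weights serialize as plain "0"
  expect_true(any(grepl("\t0$", lines) | grepl("\t0\t", lines)))
  # round-trip within formatting precision
  back <- read_term_tsv(out)
  expect_equal(as.vector(back), as.vector(unclass(toy_S)[, colnames(back)]),
               tolerance = 1e-6)
})

test_that("sample-term TSV shape and single-sample case", {
  f <- matrix(c(1, 3, 2, 2, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("C1", "C2")))
  N <- suppressWarnings(sample_matrix(f, toy_S))
  out <- tempfile(fileext = ".tsv")
  write_sample_term_tsv(N, out, ont = mini_ont)
  lines <- readLines(out)
  expect_length(lines, 4)  # header + one row per term
  expect_equal(strsplit(lines[1], "\t")[[1]], c("term_id", "term_name", "s1", "s2", "s3"))

  single <- N[1, , drop = FALSE]
  class(single) <- class(N)
  out2 <- tempfile(fileext = ".tsv")
  write_sample_term_tsv(single, out2)
  expect_equal(length(strsplit(readLines(out2)[1], "\t")[[1]]), 3)  # ids + 1 sample

  # file sums agree with in-memory sums
  back <- read_term_tsv(out)
  expect_equal(rowSums(back), rowSums(N)[rownames(back)], tolerance = 1e-6)
})

test_that("DOT output draws tagged terms, their ancestors, and is_a edges", {
  dot <- render_dot(c("E:3" = 0.7, "E:5" = 0.3), mini_ont, label = "C1")
  for (node in c("E:1", "E:2", "E:3", "E:5")) {
    expect_match(dot, paste0('"', node, '"'), fixed = TRUE)
  }
  expect_false(grepl('"E:4"', dot, fixed = TRUE))
  expect_match(dot, '"E:3" -> "E:2";', fixed = TRUE)
  expect_match(dot, '"E:2" -> "E:1";', fixed = TRUE)
  expect_match(dot, '"E:5" -> "E:1";', fixed = TRUE)
  # highest weight gets the orange end of the ramp, lowest the gray end
  e3_line <- grep('"E:3" \\[', strsplit(dot, "\n")[[1]], value = TRUE)
  e5_line <- grep('"E:5" \\[', strsplit(dot, "\n")[[1]], value = TRUE)
  expect_match(e3_line, "#FF8800")
  expect_match(e5_line, "#BDBDBD")
  # ancestor-only nodes are unfilled
  e1_line <- grep('"E:1" \\[', strsplit(dot, "\n")[[1]], value = TRUE)
  expect_match(e1_line, "style=solid")
})

test_that("DOT text is grammatically balanced, deterministic, and handles edges", {
  dot1 <- render_dot(c("E:3" = 0.7, "E:5" = 0.3), mini_ont, label = "x")
  dot2 <- render_dot(c("E:5" = 0.3, "E:3" = 0.7), mini_ont, label = "x")
  expect_identical(dot1, dot2)
  expect_match(dot1, "^digraph")
  expect_equal(lengths(regmatches(dot1, gregexpr("\\{", dot1))),
               lengths(regmatches(dot1, gregexpr("\\}", dot1))))

  root_only <- render_dot(c("E:1" = 1), mini_ont)
  expect_match(root_only, '"E:1"', fixed = TRUE)
  expect_false(grepl("->", root_only))

  empty <- render_dot(stats::setNames(numeric(0), character(0)), mini_ont)
  expect_match(empty, "digraph")
  expect_error(render_dot(c("NOPE" = 1), mini_ont), class = "envotag_lookup_error")
})

test_that("intermediates list every term per sequence, with zero-hit markers", {
  hit_table <- tibble::tibble(
    query_id = c("C1", "C1", "C2"),
    subject_id = c("gi|1|gb|A.1|", "B.1", "C.1"),
    record_id = c("1", "B.1", "C.1"),
    evalue = c(1e-30, 1e-20, 1e-10), bitscore = c(200, 150, 100),
    rank = c(1L, 2L, 1L))
  evidence <- dplyr::bind_rows(
    ev_row("C1", "1", "fresh water from lake", "10", c("E:3" = 1)),
    ev_row("C1", "B.1", "soil near fresh water", "11", c("E:5" = 1, "E:3" = 1))
  )
  dir <- tempfile()
  paths <- write_intermediates(hit_table, evidence, dir, ont = mini_ont,
                               sequence_ids = c("C1", "C2", "C3"))
  expect_true(all(file.exists(paths)))
  terms <- readr::read_tsv(paths[["terms"]], show_col_types = FALSE)
  expect_equal(sum(terms$query_id == "C1"), 2)               # E:3 and E:5
  expect_equal(terms$count[terms$query_id == "C1" & terms$term_id == "E:3"], 2)
  expect_equal(terms$term_id[terms$query_id == "C3"], "-")   # zero-hit marker
  hits <- readr::read_tsv(paths[["hits"]], show_col_types = FALSE)
  expect_equal(nrow(hits), 3)
})
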