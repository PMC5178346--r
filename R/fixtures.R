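#' Write the packaged mini ontology
#'
#' A five-term fixture ontology used throughout the tests and examples:
#' `E:1` "environmental material" as root, `E:2` "water" and `E:5` "soil"
#' beneath it, and `E:3` "fresh water" / `E:4` "sea water" beneath water.
#' The `"diamond"` variant instead writes a four-term multi-parent graph
#' (X is_a Y, X is_a Z, Y is_a W, Z is_a W) for exercising deduplicated
#' multi-path traversal. Output is byte-identical across calls.
#'
#' @param out Output OBO path.
#' @param variant `"basic"` (default) or `"diamond"`.
#' @return `out`, invisibly.
#' @export
make_mini_ontology <- function(out, variant = c("basic", "diamond")) {
  variant <- match.arg(variant)
  basic <- c(
    "format-version: 1.2",
    "ontology: envotag-mini",
    "",
    "[Term]", "id: E:1", "name: environmental material", "",
    "[Term]", "id: E:2", "name: water", "is_a: E:1 ! environmental material", "",
    "[Term]", "id: E:3", "name: fresh water", "is_a: E:2 ! water",
    'synonym: "freshwater" EXACT []', "",
    "[Term]", "id: E:4", "name: sea water", "is_a: E:2 ! water",
    'synonym: "seawater" EXACT []', 'synonym: "marine water" RELATED []', "",
    "[Term]", "id: E:5", "name: soil", "is_a: E:1 ! environmental material", "",
    "[Term]", "id: E:9", "name: obsolete lake", "is_obsolete: true", ""
  )
  diamond <- c(
    "format-version: 1.2",
    "ontology: envotag-diamond",
    "",
    "[Term]", "id: D:W", "name: substance", "",
    "[Term]", "id: D:Y", "name: liquid", "is_a: D:W", "",
    "[Term]", "id: D:Z", "name: aqueous material", "is_a: D:W", "",
    "[Term]", "id: D:X", "name: brine", "is_a: D:Y", "is_a: D:Z", ""
  )
  writeLines(if (variant == "basic") basic else diamond, out)
  invisible(out)
}

# template texts with their hand-tabulated term content (used both to build
# store rows and, independently of the tagger, to compute expected counts)
toy_templates <- function() {
  list(
    "fresh water from lake"    = c("E:3" = 1L),
    "agricultural soil"        = c("E:5" = 1L),
    "surface sea water"        = c("E:4" = 1L),
    "water from a deep well"   = c("E:2" = 1L),
    "soil near fresh water"    = c("E:5" = 1L, "E:3" = 1L),
    "hydrothermal vent fluid"  = stats::setNames(integer(0), character(0))
  )
}

#' Generate a self-contained toy dataset
#'
#' Builds every input the pipeline needs, with no download: a FASTA of random
#' nucleotide sequences, a sequence-by-sample count table with
#' log-series-like abundances, a 12-column tabular similarity-search result,
#' and a 3-column store TSV of isolation sources. The hit and store design
#' deliberately covers every pipeline branch:
#' \itemize{
#'   \item the first sequence gets 12 passing hits, exceeding the default
#'     10-target cap;
#'   \item the second sequence's four records share isolation-source texts
#'     and PubMed ids in a pattern that separates the three accumulation
#'     strategies;
#'   \item one sequence has hits individually failing the e-value, coverage
#'     and identity thresholds;
#'   \item some hit subjects are absent from the store, one store record has
#'     an empty isolation source, one text tags no ontology term, and the
#'     last sequence has no hits at all — so at least one sequence ends
#'     unannotated.
#' }
#' A machine-readable expectation file accompanies the dataset: the raw
#' per-sequence term counts under each strategy, tabulated by an independent
#' brute-force path (template bookkeeping plus base-R deduplication, no
#' tagger involved), for use as an integration-test oracle.
#'
#' All randomness is seeded and the seed is recorded in the output file
#' names; the same seed always reproduces byte-identical files.
#'
#' @param n_seqs Number of sequences (>= 7 recommended so every designed
#'   branch is present; minimum 1).
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed.
#' @param out_dir Output directory (created).
#' @return Named list of paths: `fasta`, `abundances`, `search_results`,
#'   `store_tsv`, `obo`, `expected` (JSON), plus `expected_counts` (the
#'   expectation parsed into a list `strategy -> query -> term -> count`).
#' @export
make_toy_dataset <- function(n_seqs = 10, n_samples = 3, seed = 1, out_dir) {
  if (n_seqs < 1 || n_samples < 1) {
    rlang::abort("n_seqs and n_samples must be >= 1", class = "envotag_argument_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  tag <- sprintf("toy_s%d", seed)
  paths <- list(
    fasta = file.path(out_dir, paste0(tag, ".fasta")),
    abundances = file.path(out_dir, paste0(tag, "_abundances.tsv")),
    search_results = file.path(out_dir, paste0(tag, "_hits.tsv")),
    store_tsv = file.path(out_dir, paste0(tag, "_store.tsv")),
    obo = file.path(out_dir, paste0(tag, ".obo")),
    expected = file.path(out_dir, paste0(tag, "_expected.json"))
  )
  make_mini_ontology(paths$obo)

  # --- sequences ----------------------------------------------------------
  orig_ids <- paste0("OTU_", seq_len(n_seqs))
  lens <- sample(150:250, n_seqs, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  writeLines(paste0(">", orig_ids, "\n", seqs), paths$fasta)
  new_ids <- paste0("C", seq_len(n_seqs))

  # --- abundances (log-series-like: many rare, few dominant) --------------
  counts <- matrix(
    round(stats::rlnorm(n_seqs * n_samples, meanlog = 3, sdlog = 1.2)),
    nrow = n_seqs,
    dimnames = list(orig_ids, paste0("sample_", seq_len(n_samples)))
  )
  ab <- tibble::as_tibble(counts, rownames = "sequence_id")
  readr::write_tsv(ab, paths$abundances, progress = FALSE)

  # --- hit + store design -------------------------------------------------
  templates <- toy_templates()
  term_texts <- names(templates)[lengths(templates) > 0]
  hit_rows <- list()
  store_rows <- list()
  # per query: list of record ids retained after filtering (independent
  # bookkeeping used for the expectation file)
  retained <- stats::setNames(vector("list", n_seqs), new_ids)
  rec_text <- character()   # record_id -> template text
  rec_pm <- character()     # record_id -> pubmed id ("" = absent)
  next_gi <- 1000L

  add_hit <- function(qi, record_id, gi_style, evalue, pident, aln_frac, bitscore) {
    sid <- if (gi_style) sprintf("gi|%s|gb|KX%s.1|", record_id, record_id) else record_id
    tibble::tibble(
      q = orig_ids[qi], s = sid, pident = pident,
      aln = max(1L, round(aln_frac * lens[qi])), mism = 1L, gap = 0L,
      qs = 1L, qe = lens[qi], ss = 10L, se = 10L + lens[qi],
      ev = evalue, bs = bitscore
    )
  }
  add_record <- function(record_id, text, pm) {
    rec_text[[record_id]] <<- text
    rec_pm[[record_id]] <<- pm
    store_rows[[length(store_rows) + 1L]] <<-
      tibble::tibble(record_id = record_id, isolation_source = text,
                     pubmed_id = pm)
  }

  for (qi in seq_len(n_seqs)) {
    kept <- character()
    if (qi == 1L) {
      # 12 passing hits; default cap keeps the 10 smallest e-values
      for (k in 1:12) {
        rid <- as.character(next_gi); next_gi <- next_gi + 1L
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = TRUE, evalue = k * 1e-40,
                  pident = 99.0, aln_frac = 1, bitscore = 300 - k)
        add_record(rid, term_texts[(k - 1L) %% length(term_texts) + 1L],
                   pm = as.character(7000 + k))
        if (k <= 10) kept <- c(kept, rid)
      }
    } else if (qi == 2L && n_seqs >= 2) {
      # strategy-discriminating design:
      #   A,B: same text, same pubmed; C: same text, new pubmed; D: other text
      pat <- list(
        list(text = "fresh water from lake", pm = "100"),
        list(text = "fresh water from lake", pm = "100"),
        list(text = "fresh water from lake", pm = "200"),
        list(text = "agricultural soil", pm = "300")
      )
      for (k in seq_along(pat)) {
        rid <- as.character(next_gi); next_gi <- next_gi + 1L
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = k %% 2 == 0, evalue = k * 1e-30,
                  pident = 98.5, aln_frac = 1, bitscore = 250 - k)
        add_record(rid, pat[[k]]$text, pat[[k]]$pm)
        kept <- c(kept, rid)
      }
    } else if (qi == 3L && n_seqs >= 3) {
      # one hit failing each threshold, plus two passing
      fail_specs <- list(
        list(evalue = 1e-2, pident = 99, aln_frac = 1),      # e-value fails
        list(evalue = 1e-30, pident = 99, aln_frac = 0.5),   # coverage fails
        list(evalue = 1e-30, pident = 90, aln_frac = 1)      # identity fails
      )
      for (k in seq_along(fail_specs)) {
        rid <- as.character(next_gi); next_gi <- next_gi + 1L
        sp <- fail_specs[[k]]
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = TRUE, evalue = sp$evalue,
                  pident = sp$pident, aln_frac = sp$aln_frac, bitscore = 100)
        add_record(rid, term_texts[k], pm = "")
      }
      for (k in 1:2) {
        rid <- as.character(next_gi); next_gi <- next_gi + 1L
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = FALSE, evalue = k * 1e-25,
                  pident = 99.2, aln_frac = 1, bitscore = 200 - k)
        add_record(rid, "surface sea water", pm = as.character(400 + k))
        kept <- c(kept, rid)
      }
    } else if (qi == 4L && n_seqs >= 4) {
      # two passing hits whose subjects are missing from the store + one found
      for (k in 1:2) {
        rid <- paste0("MISSING", k, ".1")
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = FALSE, evalue = k * 1e-20,
                  pident = 98.1, aln_frac = 1, bitscore = 150 - k)
        # deliberately NOT added to the store
      }
      rid <- as.character(next_gi); next_gi <- next_gi + 1L
      hit_rows[[length(hit_rows) + 1L]] <-
        add_hit(qi, rid, gi_style = TRUE, evalue = 3e-20,
                pident = 98.1, aln_frac = 1, bitscore = 147)
      add_record(rid, "water from a deep well", pm = "")
      kept <- c(kept, rid)
    } else if (qi == 5L && n_seqs >= 5) {
      # record with empty isolation source (discarded) + one informative
      rid_empty <- as.character(next_gi); next_gi <- next_gi + 1L
      hit_rows[[length(hit_rows) + 1L]] <-
        add_hit(qi, rid_empty, gi_style = TRUE, evalue = 1e-22,
                pident = 99.5, aln_frac = 1, bitscore = 180)
      add_record(rid_empty, "", pm = "500")
      rid <- as.character(next_gi); next_gi <- next_gi + 1L
      hit_rows[[length(hit_rows) + 1L]] <-
        add_hit(qi, rid, gi_style = TRUE, evalue = 2e-22,
                pident = 99.5, aln_frac = 1, bitscore = 179)
      add_record(rid, "soil near fresh water", pm = "501")
      kept <- c(kept, rid)
    } else if (qi == 6L && n_seqs >= 6) {
      # informative-looking record whose text tags no ontology term
      rid <- as.character(next_gi); next_gi <- next_gi + 1L
      hit_rows[[length(hit_rows) + 1L]] <-
        add_hit(qi, rid, gi_style = TRUE, evalue = 1e-18,
                pident = 97.5, aln_frac = 1, bitscore = 120)
      add_record(rid, "hydrothermal vent fluid", pm = "600")
      kept <- c(kept, rid)
    } else if (qi == n_seqs && n_seqs >= 7) {
      # no hits at all: guaranteed unannotated sequence
    } else {
      n_hits <- sample(1:3, 1)
      for (k in seq_len(n_hits)) {
        rid <- as.character(next_gi); next_gi <- next_gi + 1L
        hit_rows[[length(hit_rows) + 1L]] <-
          add_hit(qi, rid, gi_style = k %% 2 == 1, evalue = k * 1e-15,
                  pident = 98.0, aln_frac = 1, bitscore = 110 - k)
        add_record(rid, sample(term_texts, 1), pm = as.character(sample(900:999, 1)))
        kept <- c(kept, rid)
      }
    }
    retained[[new_ids[qi]]] <- kept
  }

  hits <- dplyr::bind_rows(hit_rows)
  readr::write_tsv(hits, paths$search_results, col_names = FALSE, progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(store_rows), paths$store_tsv, progress = FALSE)

  # --- expectation file: independent brute-force tabulation ---------------
  templates_by_text <- templates
  expected <- list()
  for (strat in c("flat", "unique_isolation", "unique_pubmed_unique_isolation")) {
    per_query <- list()
    for (q in new_ids) {
      recs <- retained[[q]]
      if (!length(recs)) next
      texts <- unname(unlist(rec_text[recs]))
      pms <- unname(unlist(rec_pm[recs]))
      keep <- switch(strat,
        flat = rep(TRUE, length(recs)),
        unique_isolation = !duplicated(trimws(texts)),
        unique_pubmed_unique_isolation =
          !duplicated(paste0(trimws(texts), "\r", ifelse(pms == "", "<absent>", pms)))
      )
      tally <- integer(0)
      for (tx in texts[keep]) {
        tc <- templates_by_text[[tx]]
        for (t in names(tc)) {
          tally[t] <- (if (t %in% names(tally)) tally[[t]] else 0L) + tc[[t]]
        }
      }
      if (length(tally)) per_query[[q]] <- as.list(tally[sort(names(tally))])
    }
    expected[[strat]] <- per_query
  }
  jsonlite::write_json(expected, paths$expected, auto_unbox = TRUE, digits = NA)

  c(paths, list(expected_counts = expected))
}
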