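#' Default hit-filtering parameters
#'
#' The species-level homolog screen keeps a hit when its e-value, query
#' coverage and identity all pass, then truncates to a maximum number of
#' targets per query. Defaults are e-value 1e-4, coverage 0.97, identity
#' 0.97 and 10 targets.
#'
#' @param max_evalue Maximum e-value (default `1e-4`).
#' @param min_coverage Minimum query coverage as a fraction in `[0, 1]`
#'   (alignment length / query length; default `0.97`).
#' @param min_identity Minimum identity as a fraction in `[0, 1]`, compared
#'   against percent identity / 100 (default `0.97`).
#' @param max_targets Maximum retained hits per query (default `10`).
#' @return A list of class `filter_params`.
#' @examples
#' filter_params()
#' @export
filter_params <- function(max_evalue = 1e-4, min_coverage = 0.97,
                          min_identity = 0.97, max_targets = 10) {
  stopifnot(max_evalue >= 0, min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1, max_targets >= 1)
  structure(
    list(max_evalue = max_evalue, min_coverage = min_coverage,
         min_identity = min_identity, max_targets = as.integer(max_targets)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params> e-value <= %g, coverage >= %g, identity >= %g, max targets %d\n",
    x$max_evalue, x$min_coverage, x$min_identity, x$max_targets))
  invisible(x)
}

tabular_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Run the nucleotide similarity search
#'
#' Drives an external aligner over the input FASTA. The aligner is any
#' executable honoring the contract
#' `<aligner> -query <fasta> -db <db> -outfmt 6 -out <results>` and emitting
#' the standard 12-column tabular format; the default is `blastn` against a
#' local database. With `threads > 1` the FASTA is chopped into that many
#' nearly equal consecutive chunks, each chunk is searched independently, and
#' the chunk outputs are concatenated in chunk order — the row set is
#' identical to a single-chunk run.
#'
#' @param fasta Path to the (renamed) input FASTA.
#' @param db Path/name of the nucleotide database handed to the aligner.
#' @param threads Number of chunks to split the input into (default 1).
#' @param out Path for the concatenated tabular results.
#' @param aligner Executable name or path (default `"blastn"`).
#' @param extra_args Additional command-line arguments passed through to the
#'   aligner.
#' @return `out`, invisibly.
#' @export
run_search <- function(fasta, db, threads = 1, out = tempfile(fileext = ".tsv"),
                       aligner = "blastn", extra_args = character()) {
  exe <- Sys.which(aligner)
  if (!nzchar(exe)) {
    rlang::abort(
      paste0("Aligner executable not found on PATH: ", aligner),
      class = "envotag_environment_error"
    )
  }
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0) {
    rlang::abort("FASTA file contains no records", class = "envotag_input_error")
  }
  threads <- max(1L, as.integer(threads))
  n_chunks <- min(threads, length(seqs))
  bounds <- split(seq_along(seqs),
                  ceiling(seq_along(seqs) * n_chunks / length(seqs)))

  chunk_outs <- character(n_chunks)
  for (ci in seq_len(n_chunks)) {
    chunk_fa <- tempfile(fileext = ".fasta")
    chunk_outs[ci] <- tempfile(fileext = ".tsv")
    if (n_chunks == 1L) {
      chunk_fa <- fasta
    } else {
      Biostrings::writeXStringSet(seqs[bounds[[ci]]], chunk_fa)
    }
    status <- suppressWarnings(system2(exe,
                      args = c("-query", shQuote(chunk_fa), "-db", shQuote(db),
                               "-outfmt", "6", "-out", shQuote(chunk_outs[ci]),
                               extra_args),
                      stdout = TRUE, stderr = TRUE))
    code <- attr(status, "status")
    if (!is.null(code) && code != 0) {
      rlang::abort(
        paste0("Aligner exited with status ", code, ":\n",
               paste(status, collapse = "\n")),
        class = "envotag_environment_error"
      )
    }
  }
  # concatenate chunk outputs in chunk order
  con <- file(out, "wb")
  on.exit(close(con), add = TRUE)
  for (f in chunk_outs) {
    if (file.exists(f) && file.size(f) > 0) {
      writeBin(readBin(f, "raw", file.size(f)), con)
    }
  }
  invisible(out)
}

#' Parse 12-column tabular similarity-search results
#'
#' Reads the standard tabular alignment layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) and joins the
#' query length so coverage can be computed.
#'
#' @param path Path to the results file (may be empty: zero hits).
#' @param query_lengths Named numeric vector mapping query id to its length
#'   in bases (typically `nchar()` of the renamed FASTA sequences).
#' @return A tibble with the 12 standard columns plus `query_length`.
#' @export
parse_tabular <- function(path, query_lengths) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Results file not found: ", path), class = "envotag_input_error")
  }
  if (file.size(path) == 0) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), 12), tabular_cols)) |>
        dplyr::mutate(dplyr::across(c("pct_identity", "aln_length", "mismatch",
                                      "gapopen", "qstart", "qend", "sstart",
                                      "send", "evalue", "bitscore"), as.numeric),
                      query_length = numeric(0)))
  }
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 12) {
    rlang::abort(
      sprintf("Expected 12 tab-separated columns, found %d (line 1)", ncol(raw)),
      class = "envotag_parse_error"
    )
  }
  raw <- raw[, 1:12]
  names(raw) <- tabular_cols
  short <- which(is.na(raw$bitscore))
  if (length(short)) {
    rlang::abort(sprintf("Row %d has fewer than 12 columns", short[1]),
                 class = "envotag_parse_error")
  }
  hits <- raw |>
    dplyr::mutate(dplyr::across(c("pct_identity", "aln_length", "mismatch",
                                  "gapopen", "qstart", "qend", "sstart", "send",
                                  "evalue", "bitscore"), as.numeric))
  if (any(is.na(hits$pct_identity) | hits$pct_identity < 0 | hits$pct_identity > 100)) {
    rlang::abort("Percent identity outside [0, 100]", class = "envotag_validation_error")
  }
  if (any(is.na(hits$evalue) | hits$evalue < 0)) {
    rlang::abort("Negative or non-numeric e-value", class = "envotag_validation_error")
  }
  if (any(is.na(hits$aln_length) | hits$aln_length < 1)) {
    rlang::abort("Alignment length below 1", class = "envotag_validation_error")
  }
  missing_q <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(missing_q)) {
    rlang::abort(
      paste0("No query length known for: ", paste(missing_q, collapse = ", ")),
      class = "envotag_input_error"
    )
  }
  hits$query_length <- as.numeric(query_lengths[hits$query_id])
  hits
}

#' Filter similarity-search hits to species-level homologs
#'
#' Applies the threshold screen (e-value, query coverage = alignment length /
#' query length, identity), then ranks each query's surviving hits by
#' ascending e-value, ties by descending bit score, further ties by subject
#' id, collapses duplicate subjects to their best-ranked occurrence, and
#' truncates to `max_targets` per query. The operation is idempotent.
#'
#' @param hits Tibble from [parse_tabular()].
#' @param params A [filter_params()] object.
#' @return A tibble (`query_id`, `subject_id`, `record_id`, `evalue`,
#'   `bitscore`, `rank`), the per-query hit table linking every query to
#'   zero, one or more database record identifiers.
#' @export
filter_hits <- function(hits, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (any(is.na(hits$query_length))) {
    rlang::abort("Missing query length", class = "envotag_input_error")
  }
  hits |>
    dplyr::filter(
      .data$evalue <= params$max_evalue,
      .data$aln_length / .data$query_length >= params$min_coverage,
      .data$pct_identity / 100 >= params$min_identity
    ) |>
    dplyr::arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_head(n = params$max_targets) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(record_id = vapply(.data$subject_id, extract_record_id, character(1))) |>
    dplyr::select("query_id", "subject_id", "record_id", "evalue", "bitscore", "rank")
}

#' Extract the database record identifier from a subject id
#'
#' Subject ids in the `gi|<digits>|...` dialect yield the GI number; any
#' other id (e.g. `accession.version`) is returned verbatim.
#'
#' @param subject_id A single non-empty subject identifier string.
#' @return The record identifier string.
#' @examples
#' extract_record_id("gi|123456|gb|AY123456.1|")
#' extract_record_id("AY123456.1")
#' @export
extract_record_id <- function(subject_id) {
  if (length(subject_id) != 1 || is.na(subject_id) || !nzchar(subject_id)) {
    rlang::abort("Empty subject id", class = "envotag_argument_error")
  }
  m <- regmatches(subject_id, regexec("^gi\\|([0-9]+)\\|", subject_id))[[1]]
  if (length(m) == 2) m[2] else subject_id
}
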