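#' Parse a FASTA file and rename sequences to placeholder ids
#'
#' Every sequence header is replaced by a placeholder "C1", "C2", "C3", ...
#' in file order, so downstream stages never see odd encodings or ambiguous
#' characters in identifiers. Original headers are truncated at the first
#' whitespace for identity matching against the abundance table; the full
#' new-id/original-id mapping is returned (and written alongside pipeline
#' outputs) so final tables can be re-labeled.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A tibble with one row per record, in file order: `new_id`,
#'   `original_id` and `sequence` (the nucleotide string, preserved
#'   byte-for-byte).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">OTU_7 sample=a", "ACGT", ">OTU_2", "GGCC"), fa)
#' parse_and_rename(fa)
#' @export
parse_and_rename <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path), class = "envotag_input_error")
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) rlang::abort(paste0("Cannot read FASTA: ", conditionMessage(e)),
                                     class = "envotag_input_error")
  )
  if (length(seqs) == 0) {
    rlang::abort("FASTA file contains no records", class = "envotag_input_error")
  }
  original <- sub("\\s.*$", "", names(seqs))
  dup <- unique(original[duplicated(original)])
  if (length(dup)) {
    rlang::abort(
      paste0("Duplicate FASTA headers (after truncation at whitespace): ",
             paste(dup, collapse = ", ")),
      class = "envotag_input_error"
    )
  }
  tibble::tibble(
    new_id = paste0("C", seq_along(seqs)),
    original_id = original,
    sequence = unname(as.character(seqs))
  )
}

#' Read a sequence-by-sample frequency (count) matrix
#'
#' The input is a tab-delimited table whose first row holds sample names and
#' whose first column holds sequence identifiers; by default rows are
#' sequences and columns are samples (the common OTU-table layout). Set
#' `transpose = TRUE` when the file has samples in rows. Internally the
#' counts are always oriented samples x sequences, matching the weighting
#' step \eqn{n'_{i,k} = \sum_j f_{i,j} s_{j,k}}.
#'
#' @param path Path to the TSV file.
#' @param transpose If `TRUE`, the file has samples as rows and sequences as
#'   columns.
#' @return A numeric matrix, samples in rows and sequences in columns, with
#'   dimnames set. All-zero tables are accepted with a warning.
#' @export
read_frequency_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Frequency matrix not found: ", path), class = "envotag_input_error")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) < 2) {
    rlang::abort("Frequency matrix needs an id column plus at least one data column",
                 class = "envotag_parse_error")
  }
  ids <- tbl[[1]]
  body <- as.matrix(tbl[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) | body == "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    rlang::abort(
      sprintf("Non-numeric cell at row '%s', column '%s' (value: '%s')",
              ids[bad[1, 1]], colnames(body)[bad[1, 2]], body[bad[1, , drop = FALSE]]),
      class = "envotag_parse_error"
    )
  }
  if (any(num < 0)) {
    rlang::abort("Frequency matrix contains negative counts", class = "envotag_parse_error")
  }
  f <- if (transpose) num else t(num)   # -> samples x sequences
  if (all(f == 0)) {
    rlang::warn("Frequency matrix is all zeros")
  }
  f
}

#' Keep the n most abundant sequences
#'
#' Ranks sequences by total frequency across samples and keeps the top `n`.
#' Ties are broken by input-file order (earlier sequence wins), so the result
#' is deterministic. The returned tibble preserves the input row order.
#'
#' @param seqs Tibble from [parse_and_rename()].
#' @param freq Samples x sequences matrix from [read_frequency_matrix()];
#'   its column names are matched against `original_id` (or `new_id`).
#' @param n Positive integer; if `n >=` the number of sequences, all are kept.
#' @param ignore_missing If `FALSE` (default), a FASTA sequence absent from
#'   the frequency matrix is an error; if `TRUE`, it is kept with total 0 and
#'   a warning.
#' @return The subset of `seqs`, input order preserved.
#' @export
filter_top_n <- function(seqs, freq, n, ignore_missing = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0) {
    rlang::abort("n must be a positive integer", class = "envotag_argument_error")
  }
  key <- if (all(seqs$original_id %in% colnames(freq))) "original_id" else "new_id"
  missing <- setdiff(seqs[[key]], colnames(freq))
  if (length(missing)) {
    msg <- paste0("Sequences absent from the frequency matrix: ",
                  paste(missing, collapse = ", "))
    if (!ignore_missing) rlang::abort(msg, class = "envotag_input_error")
    rlang::warn(paste0(msg, " (treated as total 0)"))
  }
  totals <- vapply(seqs[[key]], function(id) {
    if (id %in% colnames(freq)) sum(freq[, id]) else 0
  }, numeric(1))
  # order() is stable, so equal totals fall back to file order
  keep_idx <- sort(utils::head(order(-totals), n))
  seqs[keep_idx, , drop = FALSE]
}
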