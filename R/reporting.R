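format_weight <- function(x) {
  # 6 significant digits; exact zeros stay "0"
  ifelse(x == 0, "0", sprintf("%.6g", x))
}

restore_names <- function(ids, name_map = NULL) {
  if (is.null(name_map)) return(ids)
  idx <- match(ids, name_map$new_id)
  out <- name_map$original_id[idx]
  out[is.na(out)] <- ids[is.na(out)]
  out
}

#' Write the sequence-term matrix as TSV
#'
#' One column per input sequence (original names restored through the name
#' map when given) and one row per ontology term; the first two columns hold
#' the term id and its human-readable name. Values carry 6 significant
#' digits.
#'
#' @param S A `seq_term_matrix`.
#' @param path Output file path.
#' @param ont Optional `envo_ontology` used to resolve term names.
#' @param name_map Optional tibble with `new_id`, `original_id` columns (from
#'   [parse_and_rename()]).
#' @return `path`, invisibly.
#' @export
write_seq_term_tsv <- function(S, path, ont = NULL, name_map = NULL) {
  write_term_tsv(S, path, ont, col_ids = restore_names(rownames(S), name_map))
}

#' Write the sample-term matrix as TSV
#'
#' Columns are samples, rows are ontology terms; values are the normalized
#' weight of the term in the sample.
#'
#' @param N A `sample_term_matrix`.
#' @param path Output file path.
#' @param ont Optional `envo_ontology` used to resolve term names.
#' @return `path`, invisibly.
#' @export
write_sample_term_tsv <- function(N, path, ont = NULL) {
  write_term_tsv(N, path, ont, col_ids = rownames(N))
}

write_term_tsv <- function(M, path, ont = NULL, col_ids = rownames(M)) {
  terms <- colnames(M)
  if (length(terms) == 0) {
    rlang::warn("Term matrix has no terms; writing header-only file")
  }
  nm <- if (!is.null(ont)) term_names(ont, terms) else rep(NA_character_, length(terms))
  nm[is.na(nm)] <- ""
  header <- paste(c("term_id", "term_name", col_ids), collapse = "\t")
  body <- vapply(seq_along(terms), function(k) {
    paste(c(terms[k], nm[k], format_weight(M[, k])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a term-matrix TSV
#'
#' Inverse of [write_seq_term_tsv()]/[write_sample_term_tsv()] up to the
#' 6-significant-digit formatting.
#'
#' @param path TSV path.
#' @return Numeric matrix, rows = sequences/samples (TSV columns), columns =
#'   terms.
#' @export
read_term_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    term_id = readr::col_character(), term_name = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  m <- t(as.matrix(tbl[, -(1:2), drop = FALSE]))
  colnames(m) <- tbl$term_id
  m
}

# Fixed color ramp endpoints (hex): gray for the lowest recorded weight,
# then yellow shading to orange for increasing weights.
DOT_COLOR_MIN <- "#BDBDBD"
DOT_COLOR_MID <- "#FFEE55"
DOT_COLOR_MAX <- "#FF8800"

dot_color <- function(w, wmin, wmax) {
  if (wmax <= wmin) return(rep(DOT_COLOR_MIN, length(w)))
  t <- (w - wmin) / (wmax - wmin)
  ramp <- grDevices::colorRamp(c(DOT_COLOR_MIN, DOT_COLOR_MID, DOT_COLOR_MAX))
  rgb <- ramp(t)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Render a weighted term hierarchy as Graphviz DOT text
#'
#' Draws the tagged terms together with all of their ancestors so the
#' hierarchy is connected upward; edges are the ontology's is_a relations
#' restricted to the drawn nodes. Node fill encodes weight: the lowest
#' recorded weight is gray and increasing weights shade from yellow to
#' orange; ancestor-only nodes (weight 0) are drawn unfilled. Node and edge
#' order is sorted, so output is deterministic; the text renders with any
#' Graphviz installation (`dot -Tpdf`).
#'
#' @param term_weights Named numeric vector (names = term ids, values >= 0),
#'   or a tibble with `term_id` and a weight/count column.
#' @param ont An `envo_ontology` containing every weighted term.
#' @param label Graph label (e.g. the sequence or sample name).
#' @return A single string of DOT source.
#' @export
render_dot <- function(term_weights, ont, label = "") {
  stopifnot(inherits(ont, "envo_ontology"))
  if (is.data.frame(term_weights)) {
    wcol <- intersect(c("weight", "count"), names(term_weights))[1]
    term_weights <- stats::setNames(as.numeric(term_weights[[wcol]]),
                                    term_weights$term_id)
  }
  if (any(term_weights < 0)) {
    rlang::abort("Negative term weights", class = "envotag_validation_error")
  }
  term_weights <- term_weights[term_weights > 0]
  assert_term(ont, names(term_weights))

  nodes <- sort(unique(c(names(term_weights),
                         unlist(lapply(names(term_weights), ancestors, ont = ont)))))
  edges <- ont$edges |>
    dplyr::filter(.data$child %in% nodes, .data$parent %in% nodes) |>
    dplyr::arrange(.data$child, .data$parent)

  w <- stats::setNames(rep(0, length(nodes)), nodes)
  w[names(term_weights)] <- term_weights
  pos <- w[w > 0]
  fills <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (length(pos)) {
    fills[names(pos)] <- dot_color(pos, min(pos), max(pos))
  }
  node_lines <- vapply(nodes, function(t) {
    lbl <- sprintf("%s\\n%s\\n%.3f", t, term_names(ont, t), w[[t]])
    if (is.na(fills[[t]])) {
      sprintf('  "%s" [label="%s", style=solid];', t, lbl)
    } else {
      sprintf('  "%s" [label="%s", style=filled, fillcolor="%s"];', t, lbl, fills[[t]])
    }
  }, character(1))
  edge_lines <- if (nrow(edges)) {
    sprintf('  "%s" -> "%s";', edges$child, edges$parent)
  } else character(0)

  paste(c(
    sprintf('digraph "%s" {', gsub('"', "'", label)),
    '  rankdir=BT;',
    '  node [shape=box, fontname="Helvetica"];',
    sprintf('  label="%s";', gsub('"', "'", label)),
    node_lines,
    edge_lines,
    "}"
  ), collapse = "\n")
}

#' Write intermediary pipeline outputs
#'
#' Emits a precise per-sequence listing of every ontology term found
#' (`seq_to_terms.tsv`: sequence, term id, term name, raw count, supporting
#' record ids) and the filtered hit table (`filtered_hits.tsv`). Sequences
#' with zero tagged terms appear with an explicit `-` marker so the absence
#' of environmental information is visible.
#'
#' @param hit_table Tibble from [filter_hits()].
#' @param evidence Tibble from [collect_evidence()].
#' @param dir Output directory (created if needed).
#' @param ont Optional ontology for term names.
#' @param sequence_ids All pipeline sequence ids (so unannotated ones are
#'   listed too).
#' @param name_map Optional renaming tibble to restore original ids.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_intermediates <- function(hit_table, evidence, dir, ont = NULL,
                                sequence_ids = NULL, name_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hits_path <- file.path(dir, "filtered_hits.tsv")
  terms_path <- file.path(dir, "seq_to_terms.tsv")

  ht <- dplyr::mutate(hit_table,
                      query = restore_names(.data$query_id, name_map))
  readr::write_tsv(ht[, c("query", "query_id", "subject_id", "record_id",
                          "evalue", "bitscore", "rank")], hits_path, progress = FALSE)

  if (is.null(sequence_ids)) sequence_ids <- unique(hit_table$query_id)
  per_term <- evidence |>
    dplyr::group_by(.data$query_id, .data$term_id) |>
    dplyr::summarise(count = sum(.data$count),
                     records = paste(sort(unique(.data$record_id)), collapse = ","),
                     .groups = "drop")
  all_rows <- tibble::tibble(query_id = sequence_ids) |>
    dplyr::left_join(per_term, by = "query_id") |>
    dplyr::mutate(
      sequence = restore_names(.data$query_id, name_map),
      term_id = ifelse(is.na(.data$term_id), "-", .data$term_id),
      term_name = ifelse(.data$term_id == "-", "-",
                         if (!is.null(ont)) term_names(ont, .data$term_id) else ""),
      count = ifelse(is.na(.data$count), 0L, .data$count),
      records = ifelse(is.na(.data$records), "-", .data$records)
    ) |>
    dplyr::select("sequence", "query_id", "term_id", "term_name", "count", "records")
  readr::write_tsv(all_rows, terms_path, progress = FALSE)
  invisible(c(terms = terms_path, hits = hits_path))
}
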