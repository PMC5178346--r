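#' Collect term evidence for each query sequence
#'
#' Bridges hit filtering, the metadata store and the tagger: for every
#' retained (query, record) pair with an isolation-source text, the text is
#' tagged against the lexicon and the per-term occurrence counts recorded.
#' Records absent from the store, or whose text tags no ontology term,
#' contribute no rows.
#'
#' @param hit_table Tibble from [filter_hits()].
#' @param annotations Tibble from [lookup_many()].
#' @param lexicon An `envo_lexicon`.
#' @return An evidence tibble, one row per (query_id, record_id, term_id):
#'   columns `query_id`, `record_id`, `isolation_source`, `pubmed_id`,
#'   `term_id`, `count` (counts >= 1).
#' @export
collect_evidence <- function(hit_table, annotations, lexicon) {
  empty <- tibble::tibble(query_id = character(), record_id = character(),
                          isolation_source = character(), pubmed_id = character(),
                          term_id = character(), count = integer())
  if (nrow(hit_table) == 0 || nrow(annotations) == 0) return(empty)
  texts <- unique(annotations$isolation_source)
  tag_counts <- lapply(texts, function(tx) count_terms(tag_text(lexicon, tx)))
  names(tag_counts) <- texts
  joined <- hit_table |>
    dplyr::inner_join(annotations, by = "record_id") |>
    dplyr::select("query_id", "record_id", "isolation_source", "pubmed_id")
  out <- joined |>
    dplyr::mutate(.tags = tag_counts[.data$isolation_source]) |>
    tidyr::unnest(".tags")
  if (nrow(out) == 0) return(empty)
  out
}

strategy_names <- c("flat", "unique_isolation", "unique_pubmed_unique_isolation")

#' Accumulate per-sequence raw term counts under a deduplication strategy
#'
#' The raw count \eqn{s'_{j,k}} of term k for sequence j is the sum of that
#' term's occurrences over the isolation-source texts of the sequence's
#' retained homologs, with redundancy handled by one of three strategies:
#' \describe{
#'   \item{flat}{use raw occurrence counts from every evidence record (the
#'     default).}
#'   \item{unique_isolation}{within each query, count every identical
#'     isolation-source text only once: duplicate texts are removed before
#'     summing.}
#'   \item{unique_pubmed_unique_isolation}{within each query, keep one record
#'     per (isolation_source, pubmed_id) pair, collapsing records that carry
#'     the same text and come from the same study; a missing PubMed id acts
#'     as an explicit "absent" key.}
#' }
#' Isolation-source texts are compared exactly after trimming outer
#' whitespace (case-sensitive), avoiding over-merging of genuinely different
#' sources. Among duplicates the first record in evidence order is kept.
#'
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param strategy One of `"flat"`, `"unique_isolation"`,
#'   `"unique_pubmed_unique_isolation"` (hyphenated aliases accepted).
#' @return A tibble (`query_id`, `term_id`, `count`), counts >= 1, sorted by
#'   query then term.
#' @export
accumulate_counts <- function(evidence, strategy = "flat") {
  strategy <- gsub("-", "_", strategy)
  if (length(strategy) != 1 || !strategy %in% strategy_names) {
    rlang::abort(
      paste0("Unknown strategy '", paste(strategy, collapse = ","),
             "'; expected one of: ", paste(strategy_names, collapse = ", ")),
      class = "envotag_argument_error"
    )
  }
  empty <- tibble::tibble(query_id = character(), term_id = character(),
                          count = integer())
  if (nrow(evidence) == 0) return(empty)

  ev <- dplyr::mutate(evidence, .iso = trimws(.data$isolation_source))
  if (strategy != "flat") {
    keykey <- if (strategy == "unique_isolation") {
      paste0(ev$.iso)
    } else {
      paste0(ev$.iso, "\r", ifelse(is.na(ev$pubmed_id), "\x01<absent>", ev$pubmed_id))
    }
    # keep all term rows of the first record holding each dedup key
    keep_rec <- ev |>
      dplyr::mutate(.key = keykey) |>
      dplyr::distinct(.data$query_id, .data$.key, .keep_all = TRUE) |>
      dplyr::select("query_id", "record_id")
    ev <- dplyr::semi_join(ev, keep_rec, by = c("query_id", "record_id"))
  }
  ev |>
    dplyr::group_by(.data$query_id, .data$term_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$query_id, .data$term_id)
}

#' Propagate term counts up the ontology (backtracking)
#'
#' For every counted term t with count c, c is added once to each ancestor of
#' t; the original counts are retained. Multi-path (diamond) reachability is
#' deduplicated, so an ancestor reachable through several routes receives the
#' count exactly once per originating term. Counts never decrease, and on a
#' tree-shaped ontology the root accumulates the total original tag count.
#'
#' @param counts A tibble with columns `term_id` and `count`, and optionally
#'   `query_id` (propagation is then applied within each query).
#' @param ont An `envo_ontology`; every counted term must exist in it.
#' @return A tibble of the same shape with propagated counts.
#' @export
backtrack <- function(counts, ont) {
  stopifnot(inherits(ont, "envo_ontology"))
  assert_term(ont, unique(counts$term_id), what = "counted term")
  if (nrow(counts) == 0) return(counts)
  anc <- lapply(stats::setNames(nm = unique(counts$term_id)),
                function(t) ancestors(ont, t))
  expand <- function(df) {
    up <- df |>
      dplyr::mutate(term_id = anc[.data$term_id]) |>
      tidyr::unnest("term_id")
    dplyr::bind_rows(df, up) |>
      dplyr::group_by(.data$term_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  if ("query_id" %in% names(counts)) {
    counts |>
      dplyr::group_by(.data$query_id) |>
      dplyr::group_modify(~ expand(.x)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$query_id, .data$term_id)
  } else {
    dplyr::arrange(expand(counts), .data$term_id)
  }
}

#' Restrict counted terms to one ontology subtree
#'
#' Removes every counted term that is not the given root or one of its
#' descendants; surviving counts are untouched. Applied after backtracking,
#' this lets ancestor terms inside the subtree keep propagated weight while
#' terms from other branches are dropped.
#'
#' @param counts A tibble with a `term_id` column (e.g. from
#'   [accumulate_counts()] or [backtrack()]).
#' @param ont An `envo_ontology`.
#' @param root Term id of the subtree root.
#' @return The filtered tibble; may be empty (the sequence's row then becomes
#'   all-zero after normalization).
#' @export
apply_restriction <- function(counts, ont, root) {
  stopifnot(inherits(ont, "envo_ontology"))
  assert_term(ont, root, what = "root")
  keep <- c(root, descendants(ont, root))
  dplyr::filter(counts, .data$term_id %in% keep)
}

#' Row-normalize raw counts into the sequence-term matrix S
#'
#' Builds the matrix with one row per input sequence and one column per term
#' (columns sorted lexicographically by term id for reproducible output) and
#' divides each row by its sum: \eqn{s_{j,k} = s'_{j,k} / \sum_l s'_{j,l}}.
#' Sequences with no counted term — e.g. no homolog carried environmental
#' information, or restriction removed everything — keep an all-zero row and
#' are listed in the `unannotated` attribute.
#'
#' @param raw Tibble (`query_id`, `term_id`, `count`) of raw counts.
#' @param sequence_ids Ordered character vector of all sequence ids that must
#'   appear as rows (defaults to those present in `raw`).
#' @param term_ids Optional ordered character vector of term columns
#'   (defaults to the sorted set present in `raw`).
#' @return A numeric matrix of class `seq_term_matrix` (rows = sequences,
#'   columns = terms); attribute `unannotated` holds the ids of all-zero
#'   rows. Every nonzero row sums to 1.
#' @export
normalize_rows <- function(raw, sequence_ids = NULL, term_ids = NULL) {
  if (nrow(raw) && any(raw$count < 0)) {
    rlang::abort("Negative raw counts", class = "envotag_validation_error")
  }
  if (is.null(sequence_ids)) sequence_ids <- unique(raw$query_id)
  if (is.null(term_ids)) term_ids <- sort(unique(raw$term_id))
  S <- matrix(0, nrow = length(sequence_ids), ncol = length(term_ids),
              dimnames = list(sequence_ids, term_ids))
  if (nrow(raw)) {
    r <- raw |>
      dplyr::filter(.data$query_id %in% sequence_ids, .data$term_id %in% term_ids) |>
      dplyr::group_by(.data$query_id, .data$term_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    S[cbind(match(r$query_id, sequence_ids), match(r$term_id, term_ids))] <- r$count
  }
  sums <- rowSums(S)
  nz <- sums > 0
  S[nz, ] <- S[nz, , drop = FALSE] / sums[nz]
  structure(S, class = c("seq_term_matrix", "term_matrix", class(S)),
            unannotated = sequence_ids[!nz])
}

#' Compute the abundance-weighted sample-term matrix N
#'
#' Each biological sample is described by the sum of the term vectors of its
#' sequences weighted by their abundance:
#' \eqn{n'_{i,k} = \sum_j f_{i,j} s_{j,k}}, then row-normalized by the total,
#' \eqn{n_{i,k} = n'_{i,k} / \sum_l n'_{i,l}}, giving compositions such as
#' "Sample Z is 25% fresh water, 75% soil". Samples with all-zero weighted
#' totals keep a zero row (with a warning).
#'
#' @param freq Samples x sequences numeric matrix (from
#'   [read_frequency_matrix()], with columns renamed to the placeholder ids).
#' @param S A `seq_term_matrix`; its row set must equal `freq`'s column set.
#' @return A numeric matrix of class `sample_term_matrix` (rows = samples,
#'   columns = terms), every nonzero row summing to 1.
#' @export
sample_matrix <- function(freq, S) {
  unmatched <- c(setdiff(colnames(freq), rownames(S)), setdiff(rownames(S), colnames(freq)))
  if (length(unmatched)) {
    rlang::abort(
      paste0("Frequency matrix and sequence-term matrix disagree on sequences: ",
             paste(unique(unmatched), collapse = ", ")),
      class = "envotag_input_error"
    )
  }
  Np <- freq[, rownames(S), drop = FALSE] %*% S
  sums <- rowSums(Np)
  nz <- sums > 0
  if (any(!nz)) {
    rlang::warn(paste0("Samples with zero total term weight: ",
                       paste(rownames(Np)[!nz], collapse = ", ")))
  }
  Np[nz, ] <- Np[nz, , drop = FALSE] / sums[nz]
  structure(Np, class = c("sample_term_matrix", "term_matrix", class(Np)))
}

#' Tidy a term matrix into long format
#'
#' @param x A `seq_term_matrix` or `sample_term_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `id` (sequence or sample), `term_id`,
#'   `weight`.
#' @export
tidy.term_matrix <- function(x, ...) {
  tibble::tibble(
    id = rep(rownames(x), times = ncol(x)),
    term_id = rep(colnames(x), each = nrow(x)),
    weight = as.vector(unclass(x))
  ) |> dplyr::arrange(.data$id, .data$term_id)
}

#' One-row summary of a term matrix
#'
#' @param x A `term_matrix`.
#' @param ... Unused.
#' @return A tibble: `n_rows`, `n_terms`, `n_zero_rows`, `max_row_sum_dev`
#'   (largest absolute deviation of a nonzero row sum from 1).
#' @export
glance.term_matrix <- function(x, ...) {
  sums <- rowSums(x)
  nz <- sums > 0
  tibble::tibble(
    n_rows = nrow(x),
    n_terms = ncol(x),
    n_zero_rows = sum(!nz),
    max_row_sum_dev = if (any(nz)) max(abs(sums[nz] - 1)) else 0
  )
}

#' Heatmap of a term matrix
#'
#' @param object A `term_matrix`.
#' @param ... Unused.
#' @return A ggplot object: sequences/samples on the x axis, terms on the y
#'   axis, fill = normalized weight.
#' @export
autoplot.term_matrix <- function(object, ...) {
  df <- tidy.term_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$term_id,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey90", high = "darkorange",
                                 name = "weight") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
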