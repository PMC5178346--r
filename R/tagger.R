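#' Build a tagging lexicon from ontology names and synonyms
#'
#' Collects every term name and every retained (by default EXACT) synonym,
#' normalizes each to a lowercase token sequence, drops forms on the
#' stop-list and forms shorter than `min_chars` characters, and indexes the
#' survivors by surface form. A surface form shared by several terms maps to
#' all of them, so tagging such a form yields one hit per term.
#'
#' @param ont An `envo_ontology` from [parse_obo()].
#' @param stoplist Character vector of already-normalized (lowercase) surface
#'   forms to exclude, e.g. from [read_stoplist()]. Only exact normalized
#'   forms are removed; "water" on the stop-list does not remove "sea water".
#' @param min_chars Minimum surface-form length in characters (default 3),
#'   suppressing spurious short forms and acronyms.
#' @return An object of class `envo_lexicon`: a tibble with columns `surface`
#'   (normalized form) and `term_id`, plus attribute `max_tokens` (longest
#'   form in tokens).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' make_mini_ontology(obo)
#' lex <- build_lexicon(parse_obo(obo))
#' tag_text(lex, "fresh water from soil")
#' @export
build_lexicon <- function(ont, stoplist = character(), min_chars = 3) {
  stopifnot(inherits(ont, "envo_ontology"))
  forms <- dplyr::bind_rows(
    dplyr::select(ont$terms, "term_id", surface = "name"),
    dplyr::select(ont$synonyms, "term_id", surface = "synonym")
  ) |>
    dplyr::filter(!is.na(.data$surface)) |>
    dplyr::mutate(surface = normalize_surface(.data$surface)) |>
    dplyr::filter(nchar(.data$surface) >= min_chars,
                  !(.data$surface %in% stoplist)) |>
    dplyr::distinct(.data$surface, .data$term_id) |>
    dplyr::arrange(.data$surface, .data$term_id)
  max_tokens <- if (nrow(forms)) max(lengths(strsplit(forms$surface, " ", fixed = TRUE))) else 0L
  structure(forms, class = c("envo_lexicon", class(forms)), max_tokens = max_tokens)
}

# Lowercase and collapse every run of non-alphanumeric characters to a single
# space; matching is token-based, never substring-based.
normalize_surface <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Read a stop-list file
#'
#' One lowercase surface form per line; blank lines and lines starting with
#' `#` are ignored. The package ships a small curated default at
#' `system.file("extdata", "stoplist.txt", package = "envotag")`.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of normalized forms.
#' @export
read_stoplist <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_surface(lines))
}

#' Tag free text with ontology terms
#'
#' Dictionary-based named entity recognition over a single text. The text is
#' tokenized on non-alphanumeric boundaries and matched case-insensitively
#' against the lexicon with a leftmost-longest greedy strategy: at each token
#' position the longest matching token n-gram (up to the lexicon's
#' `max_tokens`) wins and its tokens are consumed, so "fresh water" never
#' additionally yields a "water" hit. Hits are returned in text order; a
#' surface form mapped to several terms yields one row per term with the same
#' span.
#'
#' @param lexicon An `envo_lexicon` from [build_lexicon()].
#' @param text A single character string (may be empty).
#' @return A tibble with columns `term_id`, `surface` (the matched span as it
#'   appears in `text`), `start` and `end` (0-based, half-open character
#'   offsets into `text`).
#' @export
tag_text <- function(lexicon, text) {
  stopifnot(inherits(lexicon, "envo_lexicon"), length(text) == 1)
  empty <- tibble::tibble(term_id = character(), surface = character(),
                          start = integer(), end = integer())
  if (is.na(text) || !nzchar(text) || nrow(lexicon) == 0) return(empty)

  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  tok_start <- as.integer(m)
  tok_end <- tok_start + attr(m, "match.length") - 1L
  toks <- tolower(substring(text, tok_start, tok_end))
  n <- length(toks)
  max_tokens <- attr(lexicon, "max_tokens")
  surf_map <- split(lexicon$term_id, lexicon$surface)

  out <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_tokens, n - i + 1L), 1L)) {
      form <- paste(toks[i:(i + len - 1L)], collapse = " ")
      ids <- surf_map[[form]]
      if (!is.null(ids)) {
        s <- tok_start[i] - 1L              # 0-based
        e <- tok_end[i + len - 1L]          # half-open
        out[[length(out) + 1L]] <- tibble::tibble(
          term_id = sort(ids),
          surface = substring(text, s + 1L, e),
          start = s, end = e
        )
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(out)) dplyr::bind_rows(out) else empty
}

#' Count term occurrences in a set of tag hits
#'
#' @param hits A tibble of tag hits as returned by [tag_text()] (rows from
#'   several texts may be concatenated; counts are additive).
#' @return A tibble with columns `term_id` and `count` (every count >= 1),
#'   sorted by `term_id`.
#' @export
count_terms <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble::tibble(term_id = character(), count = integer()))
  }
  hits |>
    dplyr::count(.data$term_id, name = "count") |>
    dplyr::arrange(.data$term_id)
}
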