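#' Build a local isolation-source store
#'
#' Creates the single-file SQLite store the pipeline queries offline: one
#' table `annotations(record_id TEXT PRIMARY KEY, isolation_source TEXT,
#' pubmed_id TEXT)` mapping each database record identifier (GI number or
#' accession.version) to the free-text "isolation source" field of its
#' database entry and, when known, the PubMed identifier of the study that
#' submitted it. A `meta` table records the schema version.
#'
#' @param tsv Path to a 3-column TSV with header
#'   `record_id  isolation_source  pubmed_id` (pubmed_id may be blank).
#' @param out Path for the store file (overwritten if present).
#' @return `out`, invisibly.
#' @export
build_store <- function(tsv, out) {
  tbl <- readr::read_tsv(tsv, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("record_id", "isolation_source", "pubmed_id")
  if (!all(need %in% names(tbl))) {
    rlang::abort(
      paste0("Store TSV must have columns: ", paste(need, collapse = ", ")),
      class = "envotag_parse_error"
    )
  }
  dup <- unique(tbl$record_id[duplicated(tbl$record_id)])
  if (length(dup)) {
    rlang::abort(paste0("Duplicate record_id in store TSV: ", paste(dup, collapse = ", ")),
                 class = "envotag_input_error")
  }
  tbl$pubmed_id[is.na(tbl$pubmed_id) | tbl$pubmed_id == ""] <- NA_character_
  tbl$isolation_source[is.na(tbl$isolation_source)] <- ""
  if (file.exists(out)) file.remove(out)
  con <- DBI::dbConnect(RSQLite::SQLite(), out)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', '1')")
  DBI::dbExecute(con,
    "CREATE TABLE annotations (record_id TEXT PRIMARY KEY,
                               isolation_source TEXT, pubmed_id TEXT)")
  DBI::dbWriteTable(con, "annotations", as.data.frame(tbl[, need]), append = TRUE)
  invisible(out)
}

#' Open an isolation-source store read-only
#'
#' @param path Path to a store created by [build_store()] (or any SQLite
#'   file exposing the documented `annotations` table).
#' @return A handle of class `envotag_store`.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(
      paste0("Store file not found: ", path,
             ". Build one from a 3-column TSV with build_store()."),
      class = "envotag_environment_error"
    )
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path, flags = RSQLite::SQLITE_RO)
  tabs <- DBI::dbListTables(con)
  if (!"annotations" %in% tabs) {
    DBI::dbDisconnect(con)
    rlang::abort(
      paste0("File ", path, " is not an isolation-source store ",
             "(no 'annotations' table). Rebuild it with build_store()."),
      class = "envotag_environment_error"
    )
  }
  cols <- DBI::dbListFields(con, "annotations")
  need <- c("record_id", "isolation_source", "pubmed_id")
  if (!all(need %in% cols)) {
    DBI::dbDisconnect(con)
    rlang::abort(
      paste0("Store schema mismatch; expected columns ", paste(need, collapse = ", ")),
      class = "envotag_environment_error"
    )
  }
  structure(list(con = con, path = path), class = "envotag_store")
}

#' Close a store handle
#' @param store An `envotag_store`.
#' @return `TRUE`, invisibly.
#' @export
close_store <- function(store) {
  stopifnot(inherits(store, "envotag_store"))
  DBI::dbDisconnect(store$con)
  invisible(TRUE)
}

#' @export
print.envotag_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM annotations")$n
  cat(sprintf("<envotag_store> %s (%d records)\n", x$path, n))
  invisible(x)
}

#' Look up isolation-source annotations for many record ids
#'
#' Returns annotations only for ids present in the store with a non-empty
#' isolation-source text; a record lacking that field carries no usable
#' environmental information and is silently discarded. Ids are matched
#' verbatim, so both GI digit strings and accession.version keys work.
#'
#' @param store An open `envotag_store`.
#' @param ids Character vector of record identifiers (may be empty).
#' @return A tibble (`record_id`, `isolation_source`, `pubmed_id`), one row
#'   per found id; `pubmed_id` is `NA` when absent.
#' @export
lookup_many <- function(store, ids) {
  stopifnot(inherits(store, "envotag_store"))
  empty <- tibble::tibble(record_id = character(), isolation_source = character(),
                          pubmed_id = character())
  ids <- unique(ids[!is.na(ids) & nzchar(ids)])
  if (length(ids) == 0) return(empty)
  res <- DBI::dbGetQuery(
    store$con,
    sprintf("SELECT record_id, isolation_source, pubmed_id FROM annotations
             WHERE record_id IN (%s)",
            paste(rep("?", length(ids)), collapse = ",")),
    params = as.list(ids)
  ) |> tibble::as_tibble()
  res |>
    dplyr::filter(!is.na(.data$isolation_source), nzchar(.data$isolation_source)) |>
    dplyr::arrange(match(.data$record_id, ids))
}
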