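#' Run the full environment-annotation pipeline
#'
#' Orchestrates every stage: FASTA parsing and renaming, optional
#' abundance-based top-n filtering, similarity search (or ingestion of an
#' existing tabular results file), hit filtering, isolation-source lookup,
#' ontology tagging, count accumulation under the chosen strategy, optional
#' backtracking and restriction, row normalization into the sequence-term
#' matrix and, when an abundance table was supplied, the abundance-weighted
#' sample-term matrix. All tables, per-sequence/per-sample DOT graphs,
#' intermediates, the id name map and a JSON run manifest (parameters plus
#' input checksums) are written under `out_dir`.
#'
#' The pipeline is fully deterministic: identical inputs yield byte-identical
#' outputs. When a search must be executed, its tabular result is cached in
#' `out_dir` keyed on the input checksums recorded in the manifest, so a
#' rerun with unchanged inputs skips the expensive stage.
#'
#' @param fasta Input FASTA of DNA sequences (required).
#' @param out_dir Output directory (created).
#' @param abundances Optional path to the sequence-by-sample count TSV.
#' @param transpose Set `TRUE` when the abundance TSV has samples as rows.
#' @param search_results Optional path to precomputed 12-column tabular
#'   search results; when given, no aligner is run.
#' @param db,aligner,threads Aligner settings for [run_search()] (used only
#'   when `search_results` is absent).
#' @param store Path to the isolation-source SQLite store.
#' @param obo Path to the ontology OBO file.
#' @param stoplist Optional stop-list path ([read_stoplist()] format);
#'   defaults to the packaged list.
#' @param top_n Optional: keep only the `top_n` most abundant sequences
#'   (requires `abundances`); default keeps all sequences.
#' @param params A [filter_params()] object (defaults: e-value 1e-4,
#'   coverage 0.97, identity 0.97, 10 targets).
#' @param strategy Count accumulation strategy (default `"flat"`).
#' @param backtracking Propagate counts to ancestors (default `FALSE`).
#' @param restrict Optional term id; keep only that term's subtree.
#' @param ignore_missing Tolerate FASTA sequences absent from the abundance
#'   table (see [filter_top_n()]).
#' @param verbose Print per-stage progress.
#' @return An object of class `envotag_run`: list with elements `S`
#'   (`seq_term_matrix`), `N` (`sample_term_matrix` or `NULL`), `hit_table`,
#'   `evidence`, `raw_counts`, `name_map`, `unannotated`, `manifest`, and
#'   `paths` (named vector of written files).
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' toy <- make_toy_dataset(10, 3, seed = 1, out_dir = dir)
#' store <- build_store(toy$store_tsv, file.path(dir, "store.sqlite"))
#' res <- run_pipeline(toy$fasta, file.path(dir, "out"),
#'                     abundances = toy$abundances,
#'                     search_results = toy$search_results,
#'                     store = store, obo = toy$obo)
#' glance(res$S)
#' }
#' @export
run_pipeline <- function(fasta, out_dir,
                         abundances = NULL, transpose = FALSE,
                         search_results = NULL, db = NULL,
                         aligner = "blastn", threads = 1,
                         store, obo,
                         stoplist = system.file("extdata", "stoplist.txt",
                                                package = "envotag"),
                         top_n = NULL,
                         params = filter_params(),
                         strategy = "flat",
                         backtracking = FALSE,
                         restrict = NULL,
                         ignore_missing = FALSE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[envotag] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
                   parent = e, class = "envotag_stage_error")
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("parsing and renaming FASTA")
  seqs <- stage("rename", parse_and_rename(fasta))

  freq <- NULL
  if (!is.null(abundances)) {
    say("reading frequency matrix")
    freq <- stage("abundances", read_frequency_matrix(abundances, transpose = transpose))
    if (!is.null(top_n)) {
      say("filtering to %d most abundant sequences", top_n)
      seqs <- stage("top_n", filter_top_n(seqs, freq, top_n,
                                          ignore_missing = ignore_missing))
    }
  } else if (!is.null(top_n)) {
    rlang::warn("top_n requested without an abundance table; step skipped")
  }

  manifest <- list(
    parameters = list(
      max_evalue = params$max_evalue, min_coverage = params$min_coverage,
      min_identity = params$min_identity, max_targets = params$max_targets,
      strategy = gsub("-", "_", strategy), backtracking = backtracking,
      restrict = if (is.null(restrict)) NA else restrict,
      top_n = if (is.null(top_n)) NA else top_n,
      transpose = transpose, threads = threads, aligner = aligner
    ),
    inputs = list(
      fasta = unname(tools::md5sum(fasta)),
      abundances = if (is.null(abundances)) NA else unname(tools::md5sum(abundances)),
      search_results = if (is.null(search_results)) NA else
        unname(tools::md5sum(search_results)),
      store = unname(tools::md5sum(store)),
      obo = unname(tools::md5sum(obo))
    )
  )

  # stage 3: search (or ingest)
  renamed_fa <- file.path(out_dir, "renamed.fasta")
  writeLines(paste0(">", seqs$new_id, "\n", seqs$sequence), renamed_fa)
  if (is.null(search_results)) {
    if (is.null(db)) {
      rlang::abort("Either search_results or db must be given",
                   class = "envotag_argument_error")
    }
    cache_key <- substr(tools::md5sum(renamed_fa), 1, 12)
    cached <- file.path(out_dir, paste0("search_", cache_key, ".tsv"))
    if (file.exists(cached)) {
      say("search stage cached; reusing %s", basename(cached))
    } else {
      say("running similarity search (%s, %d thread(s))", aligner, threads)
      stage("search", run_search(renamed_fa, db, threads = threads,
                                 out = cached, aligner = aligner))
    }
    search_results <- cached
    raw_hit_ids <- seqs$new_id
  } else {
    say("ingesting search results from %s", search_results)
    raw_hit_ids <- NULL
  }

  qlens <- stats::setNames(nchar(seqs$sequence), seqs$new_id)
  # supplied result files may carry original ids; map them to placeholders
  all_hits <- stage("parse_hits", {
    h <- if (file.size(search_results) > 0) {
      readr::read_tsv(search_results, col_names = FALSE,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else tibble::tibble()
    if (nrow(h) && !all(unique(h$X1) %in% names(qlens))) {
      remap <- stats::setNames(seqs$new_id, seqs$original_id)
      if (all(unique(h$X1) %in% names(remap))) {
        h$X1 <- unname(remap[h$X1])
        tmp <- tempfile(fileext = ".tsv")
        readr::write_tsv(h, tmp, col_names = FALSE, progress = FALSE)
        search_results <- tmp
      }
    }
    parse_tabular(search_results, qlens)
  })
  all_hits <- dplyr::filter(all_hits, .data$query_id %in% seqs$new_id)

  say("filtering %d hits", nrow(all_hits))
  hit_table <- stage("filter_hits", filter_hits(all_hits, params))

  say("looking up isolation sources for %d records",
      length(unique(hit_table$record_id)))
  sh <- stage("store", open_store(store))
  on.exit(close_store(sh), add = TRUE)
  annotations <- stage("lookup", lookup_many(sh, unique(hit_table$record_id)))

  say("tagging %d isolation-source texts", nrow(annotations))
  ont <- stage("ontology", parse_obo(obo))
  stop_forms <- if (!is.null(stoplist) && nzchar(stoplist) && file.exists(stoplist)) {
    read_stoplist(stoplist)
  } else character()
  lex <- stage("lexicon", build_lexicon(ont, stoplist = stop_forms))
  evidence <- stage("tagging", collect_evidence(hit_table, annotations, lex))

  say("accumulating counts (strategy: %s)", strategy)
  raw <- stage("accumulate", accumulate_counts(evidence, strategy))
  if (isTRUE(backtracking)) {
    say("backtracking counts up the ontology")
    raw <- stage("backtrack", backtrack(raw, ont))
  }
  if (!is.null(restrict)) {
    say("restricting to subtree of %s", restrict)
    raw <- stage("restrict", apply_restriction(raw, ont, restrict))
  }

  say("normalizing rows")
  S <- stage("normalize", normalize_rows(raw, sequence_ids = seqs$new_id))
  unannotated <- attr(S, "unannotated")
  if (length(unannotated)) {
    say("%d sequence(s) carry no environmental information: %s",
        length(unannotated), paste(unannotated, collapse = ", "))
  }

  N <- NULL
  if (!is.null(freq)) {
    say("computing sample-term matrix")
    f <- freq
    remap <- stats::setNames(seqs$new_id, seqs$original_id)
    if (all(colnames(f) %in% names(remap))) colnames(f) <- unname(remap[colnames(f)])
    f <- f[, intersect(colnames(f), seqs$new_id), drop = FALSE]
    N <- stage("sample_matrix", sample_matrix(f, S))
  }

  say("writing outputs to %s", out_dir)
  paths <- c(
    seq_term = file.path(out_dir, "seq_term_matrix.tsv"),
    name_map = file.path(out_dir, "name_map.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_seq_term_tsv(S, paths[["seq_term"]], ont = ont, name_map = seqs)
  readr::write_tsv(seqs[, c("new_id", "original_id")], paths[["name_map"]],
                   progress = FALSE)
  if (!is.null(N)) {
    paths[["sample_term"]] <- file.path(out_dir, "sample_term_matrix.tsv")
    write_sample_term_tsv(N, paths[["sample_term"]], ont = ont)
  }

  dot_dir <- file.path(out_dir, "graphs")
  dir.create(dot_dir, showWarnings = FALSE)
  for (j in rownames(S)) {
    w <- S[j, ]
    if (sum(w) == 0) next
    writeLines(render_dot(w[w > 0], ont, label = restore_names(j, seqs)),
               file.path(dot_dir, paste0(j, ".dot")))
  }
  if (!is.null(N)) {
    for (i in rownames(N)) {
      w <- N[i, ]
      if (sum(w) == 0) next
      writeLines(render_dot(w[w > 0], ont, label = i),
                 file.path(dot_dir, paste0("sample_", i, ".dot")))
    }
  }
  inter <- write_intermediates(hit_table, evidence, out_dir, ont = ont,
                               sequence_ids = seqs$new_id, name_map = seqs)
  paths <- c(paths, inter)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(
    list(S = S, N = N, hit_table = hit_table, evidence = evidence,
         raw_counts = raw, name_map = seqs[, c("new_id", "original_id")],
         unannotated = unannotated, manifest = manifest, paths = paths),
    class = "envotag_run"
  )
}

#' @export
print.envotag_run <- function(x, ...) {
  cat(sprintf("<envotag_run> %d sequences x %d terms", nrow(x$S), ncol(x$S)))
  if (!is.null(x$N)) cat(sprintf("; %d samples", nrow(x$N)))
  cat(sprintf("; %d unannotated\n", length(x$unannotated)))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `envotag_run`.
#' @param ... Unused.
#' @return A tibble: sequence/term/sample counts, number of unannotated
#'   sequences, number of retained hits, the strategy used.
#' @export
glance.envotag_run <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x$S),
    n_terms = ncol(x$S),
    n_samples = if (is.null(x$N)) 0L else nrow(x$N),
    n_unannotated = length(x$unannotated),
    n_hits = nrow(x$hit_table),
    strategy = x$manifest$parameters$strategy
  )
}

#' Tidy a pipeline run into the long sequence-term table
#'
#' @param x An `envotag_run`.
#' @param ... Unused.
#' @return Long tibble of per-sequence term weights (zero weights dropped),
#'   with original sequence ids restored.
#' @export
tidy.envotag_run <- function(x, ...) {
  tidy.term_matrix(x$S) |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::mutate(sequence = restore_names(.data$id, x$name_map)) |>
    dplyr::select("sequence", new_id = "id", "term_id", "weight")
}
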