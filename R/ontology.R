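#' Parse an OBO ontology file into a directed acyclic term graph
#'
#' Reads an OBO 1.2/1.4 flat file (the format the Environment Ontology is
#' distributed in) and builds the acyclic directed graph of terms connected by
#' `is_a` edges. Obsolete terms (`is_obsolete: true`) are dropped entirely and
#' contribute no edges. Only `is_a` relationships are kept; `part_of` and other
#' relationship types are ignored, so the graph is exactly the term hierarchy
#' used for count backtracking and subtree restriction.
#'
#' @param path Path to an OBO flat file. Each `[Term]` stanza must carry an
#'   `id:` line and may carry `name:`, `synonym:` and `is_a:` lines.
#' @param synonym_scopes Character vector of synonym scopes to retain.
#'   Defaults to `"EXACT"`; `BROAD`/`NARROW`/`RELATED` synonyms are excluded
#'   unless listed here.
#'
#' @return An object of class `envo_ontology`: a list with
#'   \describe{
#'     \item{terms}{tibble with columns `term_id`, `name`}
#'     \item{synonyms}{tibble with columns `term_id`, `synonym`, `scope`}
#'     \item{edges}{tibble with columns `child`, `parent` (one row per `is_a`)}
#'     \item{parents, children}{named lists giving the adjacency in each
#'       direction, for traversal}
#'   }
#'
#' @details Parsing fails with an informative error if a stanza has no `id`,
#'   if an `is_a` target does not exist as a non-obsolete term, or if the
#'   `is_a` relation contains a cycle (one offending cycle is reported).
#'
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' make_mini_ontology(obo)
#' ont <- parse_obo(obo)
#' ont
#' ancestors(ont, "E:3")
#' @export
parse_obo <- function(path, synonym_scopes = "EXACT") {
  if (!file.exists(path)) {
    rlang::abort(paste0("OBO file not found: ", path), class = "envotag_input_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")

  stanza_starts <- which(trimws(lines) == "[Term]")
  other_stanzas <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")

  terms <- list()
  synonyms <- list()
  edges <- list()

  for (s in seq_along(stanza_starts)) {
    from <- stanza_starts[s] + 1L
    ends <- c(stanza_starts, other_stanzas, length(lines) + 1L)
    to <- min(ends[ends > stanza_starts[s]]) - 1L
    if (to < from) next
    block <- lines[from:to]
    block_lines <- from:to

    id <- NULL
    name <- NA_character_
    obsolete <- FALSE
    syn <- character()
    syn_scope <- character()
    isa <- character()

    for (k in seq_along(block)) {
      ln <- trimws(block[k])
      if (ln == "" || startsWith(ln, "!")) next
      if (!grepl("^[A-Za-z_]+:", ln)) {
        rlang::abort(
          sprintf("Malformed OBO line %d: %s", block_lines[k], ln),
          class = "envotag_parse_error"
        )
      }
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[A-Za-z_]+:\\s*", "", ln))
      val <- trimws(sub("\\s*!.*$", "", val))  # strip trailing comments
      if (key == "id") {
        if (val == "") {
          rlang::abort(sprintf("Empty id at line %d", block_lines[k]),
                       class = "envotag_parse_error")
        }
        id <- val
      } else if (key == "name") {
        name <- val
      } else if (key == "is_obsolete") {
        obsolete <- identical(tolower(val), "true")
      } else if (key == "is_a") {
        isa <- c(isa, strsplit(val, "\\s+")[[1]][1])
      } else if (key == "synonym") {
        m <- regmatches(val, regexec('^"(.*)"\\s*([A-Z]*)', val))[[1]]
        if (length(m) >= 2 && nzchar(m[2])) {
          syn <- c(syn, m[2])
          syn_scope <- c(syn_scope, ifelse(nzchar(m[3]), m[3], "RELATED"))
        }
      }
    }

    if (is.null(id)) {
      rlang::abort(
        sprintf("[Term] stanza starting at line %d has no id", stanza_starts[s]),
        class = "envotag_parse_error"
      )
    }
    if (obsolete) next  # obsolete terms carry no node and no edges
    if (id %in% names(terms)) {
      rlang::abort(sprintf("Duplicate term id '%s'", id), class = "envotag_parse_error")
    }
    terms[[id]] <- tibble::tibble(term_id = id, name = name)
    if (length(syn)) {
      keep <- syn_scope %in% synonym_scopes
      if (any(keep)) {
        synonyms[[id]] <- tibble::tibble(term_id = id, synonym = syn[keep],
                                         scope = syn_scope[keep])
      }
    }
    if (length(isa)) {
      edges[[id]] <- tibble::tibble(child = id, parent = unique(isa))
    }
  }

  terms <- dplyr::bind_rows(terms)
  if (nrow(terms) == 0) {
    rlang::abort("OBO file contains no non-obsolete [Term] stanzas",
                 class = "envotag_parse_error")
  }
  synonyms <- if (length(synonyms)) dplyr::bind_rows(synonyms) else
    tibble::tibble(term_id = character(), synonym = character(), scope = character())
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(child = character(), parent = character())

  missing_parents <- setdiff(edges$parent, terms$term_id)
  if (length(missing_parents)) {
    rlang::abort(
      paste0("is_a targets missing from ontology (or obsolete): ",
             paste(sort(missing_parents), collapse = ", ")),
      class = "envotag_validation_error"
    )
  }

  ont <- new_envo_ontology(terms, synonyms, edges)
  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    rlang::abort(
      paste0("Ontology is_a relation contains a cycle: ",
             paste(cyc, collapse = " -> ")),
      class = "envotag_validation_error"
    )
  }
  ont
}

new_envo_ontology <- function(terms, synonyms, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  children <- split(edges$child, factor(edges$parent, levels = terms$term_id))
  structure(
    list(terms = terms, synonyms = synonyms, edges = edges,
         parents = parents, children = children),
    class = "envo_ontology"
  )
}

# Iterative DFS over the child->parent relation; returns one cycle as a
# character vector of term ids, or NULL if the graph is acyclic.
find_cycle <- function(ont) {
  color <- stats::setNames(rep(0L, nrow(ont$terms)), ont$terms$term_id) # 0 new, 1 open, 2 done
  for (start in ont$terms$term_id) {
    if (color[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character()
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 0L) {
        color[[node]] <- 1L
        path <- c(path, node)
      }
      nbrs <- ont$parents[[node]]
      if (top$i < length(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- nbrs[[top$i + 1L]]
        if (color[[nxt]] == 1L) {
          cut <- which(path == nxt)[1]
          return(c(path[cut:length(path)], nxt))
        }
        if (color[[nxt]] == 0L) {
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      } else {
        color[[node]] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' @export
print.envo_ontology <- function(x, ...) {
  cat(sprintf("<envo_ontology> %d terms, %d is_a edges, %d synonyms\n",
              nrow(x$terms), nrow(x$edges), nrow(x$synonyms)))
  invisible(x)
}

#' Tidy an ontology into a term table
#'
#' @param x An `envo_ontology`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term_id`, `name`, `n_parents`,
#'   `n_children`.
#' @export
tidy.envo_ontology <- function(x, ...) {
  x$terms |>
    dplyr::mutate(
      n_parents = unname(lengths(x$parents[.data$term_id])),
      n_children = unname(lengths(x$children[.data$term_id]))
    )
}

assert_term <- function(ont, term_id, what = "term") {
  bad <- setdiff(term_id, ont$terms$term_id)
  if (length(bad)) {
    rlang::abort(
      paste0("Unknown ", what, " id(s): ", paste(bad, collapse = ", ")),
      class = "envotag_lookup_error"
    )
  }
  invisible(TRUE)
}

reachable <- function(adj, start) {
  seen <- character()
  frontier <- adj[[start]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  sort(seen)
}

#' Ancestors of a term in the ontology graph
#'
#' All terms reachable from `term_id` by following `is_a` edges upward,
#' excluding the term itself. Multi-parent (diamond) paths are deduplicated:
#' each ancestor appears exactly once however many paths lead to it.
#'
#' @param ont An `envo_ontology`.
#' @param term_id A single term identifier present in the graph.
#' @return Sorted character vector of ancestor term ids (possibly empty).
#' @seealso [descendants()], [restrict_to()]
#' @export
ancestors <- function(ont, term_id) {
  stopifnot(inherits(ont, "envo_ontology"), length(term_id) == 1)
  assert_term(ont, term_id)
  reachable(ont$parents, term_id)
}

#' Descendants of a term in the ontology graph
#'
#' @inheritParams ancestors
#' @return Sorted character vector of descendant term ids (excluding
#'   `term_id` itself).
#' @export
descendants <- function(ont, term_id) {
  stopifnot(inherits(ont, "envo_ontology"), length(term_id) == 1)
  assert_term(ont, term_id)
  reachable(ont$children, term_id)
}

#' Restrict a set of terms to the subtree below one root
#'
#' Keeps only the members of `term_ids` that are the root itself or reachable
#' from the root by descending `is_a` edges; every other term is removed. This
#' implements the "restrict" option: forcing output to contain only
#' descendants of a single ontology term such as ENVO:00010483
#' ("environmental material").
#'
#' @param ont An `envo_ontology`.
#' @param root Term id of the subtree root (must exist in the graph).
#' @param term_ids Character vector of term ids to filter. Ids not present in
#'   the graph are never retained.
#' @return The subset of `term_ids`, in input order, that lie under `root`.
#' @export
restrict_to <- function(ont, root, term_ids) {
  stopifnot(inherits(ont, "envo_ontology"))
  assert_term(ont, root, what = "root")
  keep <- c(root, descendants(ont, root))
  term_ids[term_ids %in% keep]
}

term_names <- function(ont, term_ids) {
  idx <- match(term_ids, ont$terms$term_id)
  ont$terms$name[idx]
}
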