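# Shared fixtures: the 5-term mini ontology, its lexicon, and a stub aligner
# that replays a tabular hits file so no database or network is needed.

mini_ont <- local({
  obo <- tempfile(fileext = ".obo")
  make_mini_ontology(obo)
  parse_obo(obo)
})

diamond_ont <- local({
  obo <- tempfile(fileext = ".obo")
  make_mini_ontology(obo, variant = "diamond")
  parse_obo(obo)
})

mini_lexicon <- build_lexicon(mini_ont)

# Builds an envo_ontology from an explicit edge list by writing OBO text.
ontology_from_edges <- function(node_ids, edges_child, edges_parent) {
  lines <- c("format-version: 1.2", "")
  for (id in node_ids) {
    isa <- edges_parent[edges_child == id]
    isa_lines <- if (length(isa)) paste0("is_a: ", isa) else character(0)
    lines <- c(lines, "[Term]", paste0("id: ", id), paste0("name: node ", id),
               isa_lines, "")
  }
  obo <- tempfile(fileext = ".obo")
  writeLines(lines, obo)
  parse_obo(obo)
}

# Random DAG: edges only from higher-numbered to lower-numbered nodes.
random_dag <- function(n, p = 0.25) {
  ids <- paste0("T", seq_len(n))
  ec <- character(); ep <- character()
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1)) {
      if (stats::runif(1) < p) {
        ec <- c(ec, ids[i]); ep <- c(ep, ids[j])
      }
    }
  }
  list(ont = ontology_from_edges(ids, ec, ep), ids = ids,
       edges = data.frame(child = ec, parent = ep))
}

# Random tree: every non-root node has exactly one parent among earlier nodes.
random_tree <- function(n) {
  ids <- paste0("T", seq_len(n))
  ec <- ids[-1]
  ep <- ids[vapply(seq_len(n)[-1], function(i) sample.int(i - 1, 1), integer(1))]
  list(ont = ontology_from_edges(ids, ec, ep), ids = ids,
       edges = data.frame(child = ec, parent = ep))
}

# Stub aligner honoring the "-query/-db/-outfmt 6/-out" contract: emits the
# rows of the hits table (passed as -db) whose first column matches a query
# id present in the chunk FASTA.
write_stub_aligner <- function(dir = tempfile("stubbin")) {
  dir.create(dir, showWarnings = FALSE)
  exe <- file.path(dir, "stubalign")
  writeLines(c(
    "#!/bin/sh",
    'Q=""; DB=""; OUT=""',
    'while [ $# -gt 0 ]; do',
    '  case "$1" in',
    '    -query) Q="$2"; shift 2;;',
    '    -db) DB="$2"; shift 2;;',
    '    -out) OUT="$2"; shift 2;;',
    '    *) shift;;',
    '  esac',
    'done',
    ': > "$OUT"',
    "grep '^>' \"$Q\" | sed 's/^>//' | cut -f1 -d' ' | while read -r id; do",
    '  awk -F "\t" -v q="$id" \'$1 == q\' "$DB" >> "$OUT"',
    'done'
  ), exe)
  Sys.chmod(exe, "0755")
  exe
}

# Minimal evidence-row constructor used across termspace/reporting tests.
ev_row <- function(query, record, text, pm, terms) {
  tibble::tibble(query_id = query, record_id = record, isolation_source = text,
                 pubmed_id = pm, term_id = names(terms),
                 count = as.integer(terms))
}

# One toy dataset shared across integration tests (seed fixed; generation is
# deterministic).
toy <- local({
  dir <- tempfile("toy")
  make_toy_dataset(n_seqs = 10, n_samples = 3, seed = 1, out_dir = dir)
})

toy_store <- local({
  path <- tempfile(fileext = ".sqlite")
  build_store(toy$store_tsv, path)
  path
})
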