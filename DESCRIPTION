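Package: envotag
Title: Annotate DNA Sequences with Environment Ontology Terms from
    Isolation-Source Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links DNA sequences (typically OTU representative sequences) to
    the environments they have previously been observed in. Homologs of each
    input sequence are found by a nucleotide similarity search, the free-text
    "isolation source" metadata of the matching database records is collected
    from a local SQLite store, and a dictionary-based named entity recognition
    tagger maps that text onto Environment Ontology (EnvO) terms. Per-sequence
    term counts are accumulated under three deduplication strategies,
    optionally propagated up the ontology graph ("backtracking") or limited to
    the descendants of one chosen term ("restriction"), and row-normalized
    into a sequence-term matrix. When a sequence-by-sample abundance table is
    supplied, abundance-weighted summation yields a sample-term matrix
    describing each biological sample as a composition of environment terms.
    Outputs include TSV tables, Graphviz DOT renderings of the tagged term
    hierarchy, and per-sequence evidence listings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
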