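---
title: "Annotating sequences with environment ontology terms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequences with environment ontology terms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envotag)
```

## The model

Environmental annotation asks where else the organisms behind a set of DNA
sequences have been observed. `envotag` answers it by proxy: each input
sequence's close database homologs (approximate species-level matches) carry
an "isolation source" metadata field, and the vocabulary of those free-text
fields, mapped onto the Environment Ontology (EnvO), describes the range of
habitats the sequence variety has been recovered from.

Formally, let $s'_{j,k}$ be the number of times EnvO term $k$ was tagged in
the isolation-source texts of sequence $j$'s retained homologs. Rows are
normalized to compositions,

$$s_{j,k} = \frac{s'_{j,k}}{\sum_l s'_{j,l}},$$

giving the sequence-term matrix $\mathbf{S}$. With an abundance matrix
$\mathbf{F}$ ($f_{i,j}$ = count of sequence $j$ in sample $i$), each sample
is the abundance-weighted sum of its members' term vectors,

$$n'_{i,k} = \sum_j f_{i,j}\, s_{j,k}, \qquad
  n_{i,k} = \frac{n'_{i,k}}{\sum_l n'_{i,l}},$$

the sample-term matrix $\mathbf{N}$. Both matrices are compositional: every
nonzero row sums to one, and a sequence (or sample) with no usable
environmental evidence keeps an all-zero row rather than being dropped, so
absence of information stays visible.

### Assumptions

* Homology at high identity and coverage implies ecological comparability.
  This is the species-boundary heuristic common to marker-gene surveys; it
  degrades for genes under horizontal transfer or for very conserved
  regions.
* The isolation-source field, when present, is an honest one-line
  description of the sampled habitat. The field is free text and noisy; the
  dictionary tagger is deliberately conservative about it.
* Database sampling is taken as-is: habitats popular with submitters are
  over-represented, so term weights measure *recorded* occurrence, not
  ecological prevalence.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_evalue` | 1e-4 | — | discard chance alignments |
| `min_coverage` | 0.97 | fraction of query aligned | near-full-length matches only |
| `min_identity` | 0.97 | fraction identical | approximates species-level homology for short markers |
| `max_targets` | 10 | hits/query | caps database redundancy per sequence |
| `strategy` | `flat` | — | raw occurrence counts |
| `top_n` | all sequences | sequences | optional speed/abundance filter |
| `backtracking` | off | — | propagate counts to ancestors |
| `restrict` | off | term id | confine output to one subtree |

Coverage is defined as alignment length divided by *query* length. The
notion of "coverage of one sequence against the other" is directional; query
coverage was chosen because the inputs are short marker reads and query
coverage is the conventional species-boundary screen for them.

The three accumulation strategies handle database redundancy:
`flat` counts every tagged occurrence; `unique_isolation` counts each
identical isolation-source text once per sequence (collapsing bulk
submissions that paste the same description into hundreds of records);
`unique_pubmed_unique_isolation` collapses records sharing both the text and
the PubMed identifier, i.e. repeated descriptions *from the same study*,
while keeping identical texts that different studies produced independently.
The dedup key is the exact (text, PubMed id) pair — an AND of the two — with
a missing PubMed id acting as an explicit "absent" value; an OR reading
would silently merge unrelated studies that happen to share a generic
description like "soil". Texts are compared exactly after trimming outer
whitespace and case-sensitively, to avoid over-merging genuinely different
sources.

## The tagger

The named-entity recognizer is a dictionary tagger over EnvO term names and
their EXACT synonyms. Design choices, all on the side of precision:

* **Token-based matching**, never substring: "watershed" does not match
  "water". Tokens are maximal alphanumeric runs; matching is
  case-insensitive.
* **Leftmost-longest greedy resolution**: at each token position the longest
  matching n-gram wins and its tokens are consumed, so "fresh water" never
  also yields a "water" hit. The unit suite verifies this equals an
  exhaustive search over all non-overlapping segmentations on short texts.
* **No stemming or plural folding** by default — a replicable, conservative
  baseline.
* **Minimum surface length of 3 characters**, suppressing acronym noise.
* Only **EXACT** synonyms enter the lexicon; BROAD/NARROW/RELATED synonyms
  are excluded by default (configurable in `parse_obo()`), since loose
  synonyms are the main false-positive channel in dictionary NER.
* A small curated **stop-list** ships with the package (words like
  "sample", "culture", "isolate" that appear constantly in isolation-source
  text without describing an environment). Its contents are a maintained
  editorial artifact, not a derived object; users can replace it wholesale.

## The ontology graph

Only `is_a` edges are traversed; `part_of` and other relations are ignored,
matching the view of the ontology as a hierarchy of descriptive terms and
avoiding invented semantics for transitive propagation across mixed relation
types. Multiple parents are fully supported: ancestor sets are computed as
graph reachability with deduplication, so a diamond-shaped region
contributes each ancestor once. Parsing rejects cyclic `is_a` structures
outright (reporting one offending cycle) rather than tolerating them,
because both backtracking and restriction are defined only on a DAG.
Obsolete terms are dropped entirely and carry no edges.

Two ordering questions around the optional transforms were genuinely open
and are fixed as follows: counts are accumulated, then **backtracked, then
restricted, then normalized**. Restriction after backtracking lets ancestors
*inside* the restricted subtree keep weight propagated from their
descendants; normalizing last means the output rows are always
interpretable as compositions, including after restriction (which therefore
implicitly renormalizes). Backtracking before normalization also keeps the
backtracked root-count identity exact on tree ontologies (root count =
total tag count).

## Numerical and formatting choices

* Row normalization divides by the row sum; all-zero rows are left as zero
  and reported, never imputed.
* Term columns are ordered lexicographically by term id; output files are
  byte-stable across runs (verified by a determinism test). There is no
  randomness anywhere in the pipeline — all stochasticity lives in the
  fixture generator.
* TSV values carry 6 significant digits, a compact format that round-trips
  within 1e-6.
* Hit ranking ties (equal e-values) break by descending bit score, then by
  subject id; abundance ties in `top_n` filtering break by input-file
  order. Both chains exist purely for determinism.
* DOT node colors interpolate linearly in RGB from gray `#BDBDBD` (the
  lowest recorded weight) through yellow `#FFEE55` to orange `#FF8800`
  (the highest); ancestor-only nodes are unfilled. The endpoints are fixed
  hex constants; when all weights are equal everything renders gray.

## The metadata store

Isolation sources are looked up in a single-file SQLite database with one
`annotations(record_id, isolation_source, pubmed_id)` table (schema
version recorded in a `meta` table), so annotation runs need no network.
Keys are matched verbatim and may be GI digit strings or
accession.version strings — GI numbers are being phased out at NCBI, so the
store accepts both dialects. Records without a non-empty isolation source
are discarded at lookup time: they carry no usable environmental signal.
`build_store()` creates a store from a 3-column TSV; tests and examples only
ever use such locally built fixture stores.

## What the fixture generator emulates — and what it does not

`make_toy_dataset()` produces a complete, seeded input set: random
nucleotide sequences, a log-normal ("few dominant, many rare") abundance
table, a 12-column tabular hit file, and a store TSV whose texts come from
templates with known term content. The design intentionally covers every
pipeline branch: a query exceeding the 10-target cap, hits individually
failing each filter threshold, store misses, an empty isolation source, a
text tagging no term, and a hit-less sequence. An expectation file of
per-query counts per strategy is tabulated by an independent brute-force
path (template bookkeeping plus base-R deduplication) and serves as the
integration oracle.

What it does **not** emulate: real sequence homology (hit assignments are
scripted, not aligned), the extreme length and vocabulary variance of real
isolation-source text, NCBI's skewed habitat sampling, or ontology scale
(the fixture has 5 terms; EnvO has thousands). Passing tests therefore
demonstrate the *mechanics* — filtering, deduplication, propagation,
normalization, weighting, determinism — not annotation quality on real
data, which depends on the live database and the full EnvO release.

Problem sizes used by the test-suite and the acceptance script — a 10 × 3
toy dataset, random DAGs of up to 50 nodes, 100-instance normalization
sweeps, texts of up to 10 tokens — were chosen as the smallest sizes that
still exercise every branch and give the property suites room to find
counterexamples.

## Known limitations

* Tagging is English-only and does not expand abbreviations
  ("freshwater" is caught only because EnvO lists it as an EXACT synonym).
* A term mentioned negatively ("not seawater") still tags.
* `restrict` can empty a sequence's row entirely; the row is kept as zeros
  by design, but downstream ordination tools may need those rows removed.
* The sample matrix inherits compositional-data caveats: downstream
  statistics should treat rows of $\mathbf{N}$ as compositions.
* More sophisticated information-retrieval weightings (TF-IDF and kin) are
  out of scope here.
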