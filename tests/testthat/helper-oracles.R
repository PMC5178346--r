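# Independent brute-force oracles the implementation is checked against.

# Transitive closure of the child->parent relation via igraph reachability.
oracle_ancestors <- function(edges, node) {
  if (nrow(edges) == 0) return(character(0))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")])
  if (!node %in% igraph::V(g)$name) return(character(0))
  reach <- igraph::subcomponent(g, node, mode = "out")$name
  sort(setdiff(reach, node))
}

# Count propagation by per-term closure: each counted term adds its count
# once to every member of its ancestor set.
oracle_backtrack <- function(counts, edges) {
  out <- stats::setNames(as.numeric(counts$count), counts$term_id)
  for (i in seq_len(nrow(counts))) {
    for (a in oracle_ancestors(edges, counts$term_id[i])) {
      out[a] <- (if (a %in% names(out)) out[[a]] else 0) + counts$count[i]
    }
  }
  tibble::tibble(term_id = sort(names(out)),
                 count = as.numeric(out[sort(names(out))]))
}

# Exhaustive leftmost-longest oracle: enumerate every non-overlapping subset
# of candidate matches and select the canonical one by comparing match
# sequences elementwise on (start ascending, length descending), preferring
# the longer sequence on a prefix tie.
oracle_tag <- function(lexicon, text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- tolower(regmatches(text, gregexpr("[A-Za-z0-9]+", text))[[1]])
  n <- length(toks)
  forms <- unique(lexicon$surface)
  cands <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(n - i + 1)) {
      f <- paste(toks[i:(i + len - 1)], collapse = " ")
      if (f %in% forms) cands[[length(cands) + 1]] <- c(start = i, len = len)
    }
  }
  if (!length(cands)) return(character(0))
  # enumerate all non-overlapping subsets (texts are short)
  subsets <- list(list())
  for (cand in cands) {
    new <- lapply(subsets, function(s) {
      ok <- all(vapply(s, function(x) {
        cand["start"] >= x["start"] + x["len"] || x["start"] >= cand["start"] + cand["len"]
      }, logical(1)))
      if (ok) c(s, list(cand)) else NULL
    })
    subsets <- c(subsets, Filter(Negate(is.null), new))
  }
  keyed <- lapply(subsets, function(s) {
    if (!length(s)) return(list(key = numeric(0), s = s))
    ord <- order(vapply(s, `[`, numeric(1), "start"))
    s <- s[ord]
    key <- as.numeric(vapply(s, function(x) c(x["start"], -x["len"]), numeric(2)))
    list(key = key, s = s)
  })
  best <- keyed[[1]]
  for (k in keyed[-1]) {
    a <- k$key; b <- best$key
    len <- min(length(a), length(b))
    cmp <- 0L
    if (len > 0) {
      d <- a[seq_len(len)] - b[seq_len(len)]
      nz <- which(d != 0)[1]
      if (!is.na(nz)) cmp <- if (d[nz] < 0) -1L else 1L
    }
    if (cmp == 0L) cmp <- if (length(a) > length(b)) -1L else if (length(a) < length(b)) 1L else 0L
    if (cmp < 0L) best <- k
  }
  # expand each chosen span into the term ids its surface maps to
  out <- character(0)
  for (x in best$s) {
    f <- paste(toks[x["start"]:(x["start"] + x["len"] - 1)], collapse = " ")
    out <- c(out, sort(lexicon$term_id[lexicon$surface == f]))
  }
  out
}

# Element-wise double loop for the abundance-weighted sample matrix.
oracle_sample_matrix <- function(freq, S) {
  N <- matrix(0, nrow(freq), ncol(S), dimnames = list(rownames(freq), colnames(S)))
  for (i in seq_len(nrow(freq))) {
    for (k in seq_len(ncol(S))) {
      acc <- 0
      for (j in seq_len(ncol(freq))) {
        acc <- acc + freq[i, colnames(freq)[j]] * S[colnames(freq)[j], k]
      }
      N[i, k] <- acc
    }
    tot <- sum(N[i, ])
    if (tot > 0) N[i, ] <- N[i, ] / tot
  }
  N
}
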