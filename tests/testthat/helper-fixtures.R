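# Shared fixtures and independent oracles for the test suite.

.negev_test_cache <- new.env(parent = emptyenv())

# The large default-condition corpus used by the end-to-end checks; built
# once per test run.
default_corpus_10k <- function() {
  if (is.null(.negev_test_cache$corp10k))
    .negev_test_cache$corp10k <-
      generate_corpus(generator_config(n_sentences = 10000L, seed = 1L))
  .negev_test_cache$corp10k
}

default_features_10k <- function() {
  if (is.null(.negev_test_cache$rows10k))
    .negev_test_cache$rows10k <- featurize_corpus(default_corpus_10k(), "c40")
  .negev_test_cache$rows10k
}

# Small hand-built sentence: "Rac1 is not required for the activation of
# NF-kappaB ." with a nested event (E2 = regulation of E1, negated).
fig_negated_trigger_fixture <- function() {
  words <- c("Rac1", "is", "not", "required", "for", "the", "activation",
             "of", "NF-kappaB", ".")
  lemmas <- c("Rac1", "be", "not", "require", "for", "the", "activation",
              "of", "NF-kappaB", ".")
  pos <- c("NNP", "VBZ", "RB", "VBN", "IN", "DT", "NN", "IN", "NNP", ".")
  starts <- c(0L, cumsum(nchar(words) + 1L)[-length(words)])
  ends <- starts + nchar(words)
  tokens <- data.frame(text = words, lemma = lemmas, pos = pos,
                       start = starts, end = ends)
  edges <- data.frame(
    head      = c(4L, 4L, 4L, 4L, 5L, 7L, 7L, 8L, 4L),
    dependent = c(1L, 2L, 3L, 5L, 7L, 6L, 8L, 9L, 10L),
    label = c("nsubjpass", "aux", "neg", "prep", "pobj", "det", "prep",
              "pobj", "punct"))
  tree <- paste0(
    "(S (NP (NNP Rac1)) (VP (VBZ is) (RB not) (VP (VBN required)",
    " (PP (IN for) (NP (DT the) (NN activation)",
    " (PP (IN of) (NP (NNP NF-kappaB))))))) (. .))")
  parse <- parse_result(tokens, edges, tree)
  text <- paste(words, collapse = " ")
  span_of <- function(i) text_span(starts[i], ends[i], words[i])
  doc <- document("figdoc", text,
    entities = list(entity("T1", "protein", span_of(1)),
                    entity("T2", "protein", span_of(9))),
    events = list(
      bio_event("E1", "positive_regulation", span_of(7),
                list(list(role = "theme", ref = "T2", ref_type = "entity"))),
      bio_event("E2", "regulation", span_of(4),
                list(list(role = "theme", ref = "E1", ref_type = "event"),
                     list(role = "cause", ref = "T1", ref_type = "entity")),
                polarity = "negated")))
  list(doc = doc, parse = parse, tokens = tokens)
}

make_tokens <- function(words, lemmas = tolower(words),
                        pos = rep("NN", length(words))) {
  data.frame(text = words, lemma = lemmas, pos = pos)
}

# --- oracle: command relation, evaluated directly over root-to-leaf paths --
# Independent of the package's flattened-index representation: works on the
# nested tree, computing ancestor chains as path prefixes.
oracle_commands <- function(x, y, category, tree) {
  paths <- list()
  walk <- function(node, path) {
    path <- c(path, list(node))
    if (!is.null(node$token)) { paths[[node$token]] <<- path; return() }
    for (ch in node$children) walk(ch, path)
  }
  walk(tree, list())
  px <- paths[[x]]; py <- paths[[y]]
  # proper ancestors of the x leaf with the category, lowest = last
  anc_labels <- vapply(px[-length(px)], `[[`, "", "label")
  cat_pos <- which(anc_labels == category)
  if (length(cat_pos) == 0L) return(FALSE)
  lowest <- px[[max(cat_pos)]]
  # does `lowest` dominate the y leaf?  true iff it appears on y's path
  for (node in py[-length(py)]) if (identical(node, lowest)) return(TRUE)
  FALSE
}

# Enumerate all binary tree shapes with n leaves (Catalan many).
binary_shapes <- function(n) {
  if (n == 1L) return(list("leaf"))
  out <- list()
  for (k in seq_len(n - 1L))
    for (l in binary_shapes(k))
      for (r in binary_shapes(n - k))
        out[[length(out) + 1L]] <- list(l, r)
  out
}

# Turn a shape into a parse_result with the given internal-node labels
# (recycled in preorder).
shape_to_parse <- function(shape, labels) {
  leaf_no <- 0L; lab_no <- 0L
  build <- function(s) {
    if (identical(s, "leaf")) {
      leaf_no <<- leaf_no + 1L
      return(list(label = "X", token = leaf_no,
                  surface = paste0("w", leaf_no)))
    }
    lab_no <<- lab_no + 1L
    lab <- labels[((lab_no - 1L) %% length(labels)) + 1L]
    list(label = lab, children = list(build(s[[1]]), build(s[[2]])))
  }
  tree <- build(shape)
  n <- leaf_no
  tokens <- data.frame(text = paste0("w", seq_len(n)),
                       lemma = paste0("w", seq_len(n)),
                       pos = rep("X", n))
  parse_result(tokens,
               data.frame(head = integer(), dependent = integer(),
                          label = character()),
               tree)
}

# --- oracle: exhaustive n-gram scan for cue matching ----------------------
# Enumerates every (entry, start) candidate first, then sweeps left to
# right taking the longest non-overlapping candidate at each point.
oracle_match_cues <- function(tokens, lexicon) {
  lem <- tolower(tokens$lemma); surf <- tolower(tokens$text)
  n <- nrow(tokens)
  entries <- lexicon$entries[order(-vapply(lexicon$entries,
                                           function(e) length(e$lemmas), 1L))]
  cands <- list()
  for (ei in seq_along(entries)) {
    e <- entries[[ei]]
    k <- length(e$lemmas)
    for (i in seq_len(max(0L, n - k + 1L))) {
      idx <- i:(i + k - 1L)
      if (!all(lem[idx] == e$lemmas | surf[idx] == e$lemmas)) next
      last_pos <- tokens$pos[i + k - 1L]
      ok <- is.na(e$pos) ||
        (e$pos == "noun" && startsWith(last_pos, "NN")) ||
        (e$pos == "verb" && startsWith(last_pos, "VB"))
      if (ok) cands[[length(cands) + 1L]] <-
          list(display = e$display, first = i, last = i + k - 1L, rank = ei)
    }
  }
  if (length(cands) == 0L)
    return(data.frame(display = character(), first = integer(),
                      last = integer(), deactivated = logical()))
  ord <- order(vapply(cands, `[[`, 1L, "first"),
               -vapply(cands, function(c) c$last - c$first, 1L),
               vapply(cands, `[[`, 1L, "rank"))
  cands <- cands[ord]
  taken <- rep(FALSE, n); out <- list()
  for (cd in cands) {
    if (any(taken[cd$first:cd$last])) next
    taken[cd$first:cd$last] <- TRUE
    out[[length(out) + 1L]] <-
      data.frame(display = cd$display, first = cd$first, last = cd$last,
                 deactivated = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$first), , drop = FALSE]
}

# Random token sequences mixing content words, cue lemmas and inflections.
random_cue_sentence <- function() {
  pool <- list(
    list("STAT1", "STAT1", "NNP"), list("IL-2", "IL-2", "NNP"),
    list("the", "the", "DT"), list("of", "of", "IN"),
    list("in", "in", "IN"), list("activates", "activate", "VBZ"),
    list("binds", "bind", "VBZ"), list("not", "not", "RB"),
    list("no", "no", "DT"), list("cannot", "cannot", "MD"),
    list("could", "could", "MD"), list("fails", "fail", "VBZ"),
    list("failed", "fail", "VBD"), list("lack", "lack", "NN"),
    list("lack", "lack", "VBP"), list("lacks", "lack", "VBZ"),
    list("absence", "absence", "NN"), list("without", "without", "IN"),
    list("never", "never", "RB"), list("only", "only", "RB"),
    list("evidence", "evidence", "NN"), list("rather", "rather", "RB"),
    list("than", "than", "IN"), list("exception", "exception", "NN"),
    list("with", "with", "IN"), list("longer", "longer", "RB"),
    list("instead", "instead", "RB"), list("rule", "rule", "VB"),
    list("out", "out", "RP"), list("unaffected", "unaffected", "JJ"))
  n <- sample(3:12, 1)
  rows <- pool[sample(seq_along(pool), n, replace = TRUE)]
  data.frame(text = vapply(rows, `[[`, "", 1),
             lemma = vapply(rows, `[[`, "", 2),
             pos = vapply(rows, `[[`, "", 3))
}
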