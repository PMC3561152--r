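# ---------------------------------------------------------------------------
# Parse layer
#
# A ParseResult bundles, for one sentence: tokens (text/lemma/POS and
# document-absolute character offsets), an (undirected-for-path-purposes)
# dependency edge list, and a constituency tree.  Any
# tokenizer+tagger+dependency+constituency stack can stand behind the
# backend contract; all shipped tests run on the deterministic fixture
# backend so no parser models are required.
# ---------------------------------------------------------------------------

#' Construct a parse result
#'
#' @param tokens Data frame with columns `text`, `lemma`, `pos` and
#'   (optionally) document-absolute character offsets `start`, `end`
#'   (0-based half-open).  Rows are 1-based token positions.
#' @param edges Data frame with columns `head`, `dependent` (1-based token
#'   indices, `head != dependent`) and `label`.
#' @param tree Constituency tree: nested `list(label =, children =)` with
#'   leaves `list(label = <POS>, token = <index>)`, or a Penn-style
#'   bracketed string.  The tree yield must equal the token sequence.
#' @return An object of class `"negev_parse"`.
#' @export
parse_result <- function(tokens, edges, tree) {
  if (is.character(tree)) tree <- read_bracket_tree(tree)
  n <- nrow(tokens)
  if (n > 0L) {
    yield <- tree_yield(tree)
    if (!identical(yield, seq_len(n)))
      stop("tree yield (", paste(yield, collapse = ","),
           ") does not equal token sequence 1..", n)
  }
  if (nrow(edges)) {
    stopifnot(all(edges$head >= 1L & edges$head <= n),
              all(edges$dependent >= 1L & edges$dependent <= n),
              all(edges$head != edges$dependent))
  }
  structure(list(tokens = tokens, edges = edges, tree = tree,
                 index = index_tree(tree)),
            class = "negev_parse")
}

#' @export
print.negev_parse <- function(x, ...) {
  cat("<negev_parse> ", nrow(x$tokens), " tokens: ",
      paste(x$tokens$text, collapse = " "), "\n", sep = "")
  invisible(x)
}

# --- Penn-style bracketed trees -------------------------------------------

#' Read a Penn-style bracketed constituency tree
#'
#' Leaves are `(POS surface)`; token indices are assigned left to right.
#'
#' @param s Bracketed string, e.g. `"(S (NP (NNP Rac1)) (VP (VBZ binds)))"`.
#' @return A nested tree list (see [parse_result()]).
#' @export
read_bracket_tree <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L; leaf_no <- 0L
  parse_node <- function() {
    stopifnot(toks[pos] == "(")
    pos <<- pos + 1L
    label <- toks[pos]; pos <<- pos + 1L
    if (toks[pos] != "(" && toks[pos] != ")") {     # leaf: (POS surface)
      surface <- toks[pos]; pos <<- pos + 1L
      stopifnot(toks[pos] == ")"); pos <<- pos + 1L
      leaf_no <<- leaf_no + 1L
      return(list(label = label, token = leaf_no, surface = surface))
    }
    children <- list()
    while (toks[pos] == "(") children[[length(children) + 1L]] <- parse_node()
    stopifnot(toks[pos] == ")"); pos <<- pos + 1L
    list(label = label, children = children)
  }
  parse_node()
}

#' Serialize a tree to Penn bracket notation
#' @param tree A tree node (see [parse_result()]).
#' @param tokens Optional token data frame supplying leaf surfaces.
#' @return A single bracketed string.
#' @export
write_bracket_tree <- function(tree, tokens = NULL) {
  walk <- function(node) {
    if (!is.null(node$token)) {
      surf <- if (!is.null(node$surface)) node$surface
              else tokens$text[node$token]
      return(paste0("(", node$label, " ", surf, ")"))
    }
    paste0("(", node$label, " ",
           paste(vapply(node$children, walk, ""), collapse = " "), ")")
  }
  walk(tree)
}

tree_yield <- function(tree) {
  if (!is.null(tree$token)) return(tree$token)
  unlist(lapply(tree$children, tree_yield))
}

# Flatten a tree into an indexed table: one row per node with parent links
# and covered token ranges.  Node 1 is the root.
index_tree <- function(tree) {
  rows <- list()
  walk <- function(node, parent) {
    id <- length(rows) + 1L
    rows[[id]] <<- list(id = id, parent = parent, label = node$label,
                        is_leaf = !is.null(node$token),
                        token = if (!is.null(node$token)) node$token else NA_integer_,
                        first = NA_integer_, last = NA_integer_)
    if (is.null(node$token))
      for (ch in node$children) walk(ch, id)
    id
  }
  walk(tree, NA_integer_)
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  # token ranges bottom-up
  for (i in rev(seq_len(nrow(df)))) {
    if (df$is_leaf[i]) { df$first[i] <- df$token[i]; df$last[i] <- df$token[i] }
    kids <- which(df$parent == df$id[i])
    if (length(kids)) {
      df$first[i] <- min(df$first[kids]); df$last[i] <- max(df$last[kids])
    }
  }
  df
}

ancestors_of <- function(index, id) {
  out <- integer()
  p <- index$parent[id]
  while (!is.na(p)) { out <- c(out, p); p <- index$parent[p] }
  out
}

leaf_id <- function(index, token) {
  id <- index$id[index$is_leaf & index$token == token]
  if (length(id) != 1L) stop("no leaf for token index ", token)
  id
}

#' Proper dominance between tree nodes
#'
#' @param parse A [parse_result()].
#' @param ancestor,descendant Node ids in `parse$index` (row ids of the
#'   flattened tree; node 1 is the root).
#' @return `TRUE` iff `descendant` lies in the proper subtree of
#'   `ancestor` (a node does not dominate itself).
#' @export
dominates <- function(parse, ancestor, descendant) {
  idx <- parse$index
  if (ancestor > nrow(idx) || descendant > nrow(idx))
    stop("node id outside this tree")
  ancestor %in% ancestors_of(idx, descendant)
}

#' Command relation between two tokens
#'
#' A node X commands a node Y under category C iff neither X nor Y dominates
#' the other and the lowest C-labelled node properly dominating X also
#' dominates Y.  For two distinct leaves neither ever dominates the other,
#' so the relation reduces to: does x's lowest S (or VP, NP) ancestor also
#' dominate y?  Returns `FALSE` (not an error) when x has no ancestor of
#' the category.
#'
#' @param x,y Distinct 1-based token indices.
#' @param category `"S"`, `"VP"` or `"NP"`.
#' @param parse A [parse_result()].
#' @return Logical.
#' @export
commands <- function(x, y, category, parse) {
  stopifnot(x != y)
  category <- match.arg(category, c("S", "VP", "NP"))
  idx <- parse$index
  anc <- ancestors_of(idx, leaf_id(idx, x))       # bottom-up order
  cat_anc <- anc[idx$label[anc] == category]
  if (length(cat_anc) == 0L) return(FALSE)
  lowest <- cat_anc[1L]
  y_leaf <- leaf_id(idx, y)
  lowest %in% ancestors_of(idx, y_leaf)
}

#' Shortest dependency path between two tokens
#'
#' The dependency graph is treated as undirected; edge labels are reported
#' in traversal order with direction markers (`">"` head-to-dependent,
#' `"<"` dependent-to-head).
#'
#' @param a,b 1-based token indices.
#' @param parse A [parse_result()].
#' @return `list(exists, length, labels, direct)`; `direct` iff the path is
#'   a single edge.  When `a` and `b` are disconnected, `exists = FALSE`
#'   and `length = NA`.
#' @export
dep_path <- function(a, b, parse) {
  n <- nrow(parse$tokens)
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  if (a == b)
    return(list(exists = TRUE, length = 0L, labels = character(),
                direct = FALSE))
  e <- parse$edges
  adj <- vector("list", n)
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    h <- e$head[i]; d <- e$dependent[i]; lb <- e$label[i]
    adj[[h]] <- c(adj[[h]], list(list(to = d, lab = paste0(">", lb))))
    adj[[d]] <- c(adj[[d]], list(list(to = h, lab = paste0("<", lb))))
  }
  prev <- rep(NA_integer_, n); plab <- rep(NA_character_, n)
  seen <- rep(FALSE, n); seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == b) break
    for (nb in adj[[v]]) if (!seen[nb$to]) {
      seen[nb$to] <- TRUE; prev[nb$to] <- v; plab[nb$to] <- nb$lab
      queue <- c(queue, nb$to)
    }
  }
  if (!seen[b])
    return(list(exists = FALSE, length = NA_integer_, labels = character(),
                direct = FALSE))
  labels <- character(); v <- b
  while (v != a) { labels <- c(plab[v], labels); v <- prev[v] }
  list(exists = TRUE, length = length(labels), labels = labels,
       direct = length(labels) == 1L)
}

#' Syntactic scope of a negation cue
#'
#' The scope runs from the cue's first token to the last token of the
#' smallest S-labelled constituent dominating the cue (the whole sentence
#' when no S ancestor exists).  This cue-to-end-of-clause convention is the
#' dominant one in the scope-detection literature; it is isolated here so
#' alternatives can be swapped in.
#'
#' @param cue One row of a [match_cues()] result (`first`/`last` token
#'   indices).
#' @param parse A [parse_result()].
#' @return `c(first, last)` inclusive token range; always contiguous and
#'   containing the cue, never exceeding sentence bounds.
#' @export
cue_scope <- function(cue, parse) {
  idx <- parse$index
  anc <- ancestors_of(idx, leaf_id(idx, cue$first))
  s_anc <- anc[idx$label[anc] == "S"]
  end <- if (length(s_anc)) idx$last[s_anc[1L]] else nrow(parse$tokens)
  c(cue$first, max(cue$first, end))
}

#' Head token of a token span
#'
#' The head is the token inside the span whose dependency head lies outside
#' the span (or which has no incoming edge); ties are broken by taking the
#' rightmost such token.  Standard head-percolation heuristic.
#'
#' @param first,last Inclusive 1-based token range.
#' @param parse A [parse_result()].
#' @return A single token index.
#' @export
span_head <- function(first, last, parse) {
  span <- first:last
  if (length(span) == 1L) return(first)
  e <- parse$edges
  heads_of <- function(tok) e$head[e$dependent == tok]
  external <- vapply(span, function(tok) {
    h <- heads_of(tok)
    length(h) == 0L || any(!(h %in% span))
  }, logical(1))
  cand <- span[external]
  if (length(cand) == 0L) cand <- span
  max(cand)
}

# --- Backends --------------------------------------------------------------

#' Fixture parse backend
#'
#' A deterministic backend backed by pre-computed parses keyed by exact
#' sentence text.  A miss raises an explicit missing-fixture error — never a
#' silent fallback.
#'
#' @param parses Named list of [parse_result()]s; names are sentence texts.
#' @return An object of class `"negev_backend"`.
#' @export
fixture_backend <- function(parses) {
  stopifnot(is.list(parses), !is.null(names(parses)))
  structure(list(kind = "fixture", parses = parses),
            class = "negev_backend")
}

#' Parse one sentence through a backend
#'
#' Deterministic for a fixed backend and input.
#'
#' @param sentence_text The exact sentence string.
#' @param backend A backend object (see [fixture_backend()]).
#' @return A [parse_result()].
#' @export
parse_sentence <- function(sentence_text, backend) {
  stopifnot(inherits(backend, "negev_backend"))
  if (backend$kind == "fixture") {
    p <- backend$parses[[sentence_text]]
    if (is.null(p))
      stop("missing parse fixture for sentence: '", sentence_text, "'")
    return(p)
  }
  stop("unknown backend kind: ", backend$kind)
}

#' Fixture backend over a synthetic corpus
#'
#' Convenience constructor using the parses emitted alongside a generated
#' corpus (see [generate_corpus()]).
#'
#' @param corpus A `"negev_corpus"`.
#' @return A `"negev_backend"`.
#' @export
corpus_backend <- function(corpus) {
  stopifnot(inherits(corpus, "negev_corpus"))
  fixture_backend(corpus$parses)
}
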