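simple_parse <- function() {
  # (S (NP x) (VP v (NP y)))
  tokens <- make_tokens(c("x", "v", "y"), pos = c("NN", "VB", "NN"))
  parse_result(tokens,
               data.frame(head = c(2L, 2L), dependent = c(1L, 3L),
                          label = c("nsubj", "dobj")),
               "(S (NP (NN x)) (VP (VB v) (NP (NN y))))")
}

test_that("bracketed trees round-trip and yield the token sequence", {
  s <- "(S (NP (NNP Rac1)) (VP (VBZ binds) (NP (NNP Cdc42))))"
  tree <- read_bracket_tree(s)
  tokens <- make_tokens(c("Rac1", "binds", "Cdc42"),
                        pos = c("NNP", "VBZ", "NNP"))
  expect_identical(write_bracket_tree(tree, tokens), s)
  p <- parse_result(tokens, data.frame(head = 2L, dependent = 1L,
                                       label = "nsubj"), s)
  expect_s3_class(p, "negev_parse")
  # yield mismatch is rejected
  expect_error(parse_result(tokens[1:2, ],
                            data.frame(head = integer(), dependent = integer(),
                                       label = character()), s),
               "yield")
  # one-token sentence: a single leaf
  p1 <- parse_result(make_tokens("Go", pos = "VB"),
                     data.frame(head = integer(), dependent = integer(),
                                label = character()),
                     "(VP (VB Go))")
  expect_equal(nrow(p1$index), 2)   # VP node + leaf
})

test_that("dominance is proper and rejects foreign nodes", {
  p <- simple_parse()
  root <- 1L
  leaves <- p$index$id[p$index$is_leaf]
  for (lf in leaves) expect_true(dominates(p, root, lf))
  expect_false(dominates(p, root, root))       # no self-dominance
  for (lf in leaves) expect_false(dominates(p, lf, root))
  expect_error(dominates(p, 1L, 99L), "outside")
})

test_that("command relations on the canonical example", {
  p <- simple_parse()
  expect_true(commands(1, 3, "S", p))    # S over x dominates y
  expect_false(commands(1, 3, "NP", p))  # lowest NP over x excludes y
  expect_true(commands(3, 1, "S", p))
  expect_true(commands(2, 3, "VP", p))
  expect_false(commands(1, 3, "VP", p))  # x has no VP ancestor
  expect_error(commands(2, 2, "S", p))
})

test_that("command agrees with the path-prefix oracle on enumerated trees", {
  set.seed(77)
  labels_pool <- c("S", "VP", "NP", "X")
  for (n in 2:5) {
    shapes <- binary_shapes(n)
    for (sh in shapes) {
      labels <- sample(labels_pool, 2 * n - 1, replace = TRUE)
      labels[1] <- "S"                      # rooted sentences
      p <- shape_to_parse(sh, labels)
      for (x in seq_len(n)) for (y in seq_len(n)) {
        if (x == y) next
        for (cat in c("S", "VP", "NP")) {
          expect_identical(commands(x, y, cat, p),
                           oracle_commands(x, y, cat, p$tree))
        }
      }
    }
  }
})

test_that("dependency paths match breadth-first expectations", {
  p <- simple_parse()
  expect_identical(dep_path(1, 1, p)$length, 0L)
  d <- dep_path(1, 2, p)
  expect_true(d$direct); expect_equal(d$length, 1L)
  expect_equal(d$labels, "<nsubj")
  d2 <- dep_path(1, 3, p)
  expect_false(d2$direct); expect_equal(d2$length, 2L)
  # symmetry of length
  expect_equal(dep_path(3, 1, p)$length, dep_path(1, 3, p)$length)
  # disconnected tokens
  tokens <- make_tokens(c("a", "b", "c"))
  p2 <- parse_result(tokens,
                     data.frame(head = 1L, dependent = 2L, label = "dep"),
                     "(S (X a) (X b) (X c))")
  d3 <- dep_path(1, 3, p2)
  expect_false(d3$exists); expect_true(is.na(d3$length))
})

test_that("dependency paths agree with an igraph all-pairs oracle", {
  skip_if_not_installed("igraph")
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    m <- sample(0:(n + 2), 1)
    edges <- NULL
    if (m > 0) {
      h <- sample(n, m, replace = TRUE)
      d <- sample(n, m, replace = TRUE)
      keep <- h != d
      edges <- data.frame(head = h[keep], dependent = d[keep],
                          label = rep("dep", sum(keep)))
    }
    if (is.null(edges) || nrow(edges) == 0L)
      edges <- data.frame(head = integer(), dependent = integer(),
                          label = character())
    flat <- paste0("(S ", paste0("(X w", seq_len(n), ")", collapse = " "), ")")
    p <- parse_result(make_tokens(paste0("w", seq_len(n)), pos = rep("X", n)),
                      edges, flat)
    g <- igraph::graph_from_data_frame(
      data.frame(from = c(edges$head, n), to = c(edges$dependent, n)),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    dist <- igraph::distances(g)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      got <- dep_path(a, b, p)
      want <- dist[as.character(a), as.character(b)]
      if (is.infinite(want)) expect_false(got$exists)
      else expect_equal(got$length, as.integer(want))
    }
  }
})

test_that("cue scope runs from the cue to the end of its clause", {
  # embedded clause: (S (NP a) (VP said (SBAR that (S (NP b) (VP not c))) d))
  tokens <- make_tokens(c("a", "said", "that", "b", "not", "c", "d"),
                        pos = c("NN", "VBD", "IN", "NN", "RB", "VB", "NN"))
  tree <- paste0("(S (NP (NN a)) (VP (VBD said)",
                 " (SBAR (IN that) (S (NP (NN b)) (VP (RB not) (VB c))))",
                 " (NN d)))")
  p <- parse_result(tokens, data.frame(head = integer(),
                                       dependent = integer(),
                                       label = character()), tree)
  sc <- cue_scope(list(first = 5L, last = 5L), p)
  expect_equal(sc, c(5L, 6L))     # ends at the embedded clause, not at d
  # sentence-final cue: scope is the cue itself
  sc2 <- cue_scope(list(first = 7L, last = 7L), p)
  expect_equal(sc2, c(7L, 7L))
  # property: contiguous, starts at cue, inside sentence
  for (i in 1:7) {
    sc3 <- cue_scope(list(first = i, last = i), p)
    expect_equal(sc3[1], i)
    expect_gte(sc3[2], sc3[1])
    expect_lte(sc3[2], nrow(tokens))
  }
})

test_that("the span head is the token governed from outside the span", {
  fix <- fig_negated_trigger_fixture()
  # "the activation" span: activation (7) is governed by "for" outside
  expect_equal(span_head(6, 7, fix$parse), 7L)
  expect_equal(span_head(4, 4, fix$parse), 4L)
})

test_that("the fixture backend is exact and never falls back silently", {
  corp <- generate_corpus(generator_config(n_sentences = 20, seed = 9))
  bk <- corpus_backend(corp)
  stext <- names(corp$parses)[1]
  expect_identical(parse_sentence(stext, bk), corp$parses[[stext]])
  expect_error(parse_sentence("this sentence has no fixture", bk),
               "missing parse fixture")
})
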