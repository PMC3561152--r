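test_that("the packaged lexicons load with their published sizes", {
  expect_length(load_lexicon("c40")$entries, 40)
  expect_length(load_lexicon("cBioScope")$entries, 28)
  expect_length(load_lexicon("cBioInfer")$entries, 25)
  # printed size says 20, but 19 elements are listed; we package the list
  expect_length(load_lexicon("cCore")$entries, 19)
  expect_error(load_lexicon("c99"), "c40")
})

test_that("the core list is a subset of the combined list", {
  d40 <- vapply(load_lexicon("c40")$entries, `[[`, "", "display")
  dcore <- vapply(load_lexicon("cCore")$entries, `[[`, "", "display")
  expect_true(all(dcore %in% d40))
})

test_that("cues match by lemma, case-insensitively", {
  tk <- make_tokens(c("Rac1", "is", "not", "required", "for", "activation"),
                    c("Rac1", "be", "not", "require", "for", "activation"),
                    c("NNP", "VBZ", "RB", "VBN", "IN", "NN"))
  m <- match_cues(tk, load_lexicon("c40"))
  expect_equal(nrow(m), 1)
  expect_equal(m$display, "not")
  expect_equal(m$first, 3)
  # inflected surface resolves through the lemma
  tk2 <- make_tokens(c("STAT1", "fails", "to", "bind"),
                     c("STAT1", "fail", "to", "bind"),
                     c("NNP", "VBZ", "TO", "VB"))
  expect_equal(match_cues(tk2, load_lexicon("c40"))$display, "fail")
  # no cue at all
  tk3 <- make_tokens(c("the", "protein", "activates", "the", "gene"),
                     pos = c("DT", "NN", "VBZ", "DT", "NN"))
  expect_equal(nrow(match_cues(tk3, load_lexicon("c40"))), 0)
  expect_equal(nrow(match_cues(tk3[0, ], load_lexicon("c40"))), 0)
})

test_that("multi-word entries outrank their sub-spans", {
  tk <- make_tokens(c("the", "complex", "could", "not", "form"),
                    c("the", "complex", "could", "not", "form"),
                    c("DT", "NN", "MD", "RB", "VB"))
  m <- match_cues(tk, load_lexicon("cBioScope"))
  expect_equal(m$display, "could not")
  expect_equal(c(m$first, m$last), c(3, 4))
  # 4-lemma entry wins over its nested "except"
  tk2 <- make_tokens(c("with", "the", "exception", "of", "STAT1"),
                     pos = c("IN", "DT", "NN", "IN", "NNP"))
  m2 <- match_cues(tk2, load_lexicon("cBioScope"))
  expect_equal(m2$display, "with the exception of")
})

test_that("POS-constrained entries respect the tag", {
  core <- load_lexicon("cCore")
  tk_noun <- make_tokens(c("a", "lack", "of", "expression"),
                         pos = c("DT", "NN", "IN", "NN"))
  m <- match_cues(tk_noun, core)
  expect_equal(m$display, "lack (noun)")
  tk_verb <- make_tokens(c("cells", "lack", "STAT1"),
                         c("cell", "lack", "STAT1"),
                         c("NNS", "VBP", "NNP"))
  expect_equal(match_cues(tk_verb, core)$display, "lack (verb)")
  tk_adj <- make_tokens("lack", pos = "JJ")      # incompatible with both
  expect_equal(nrow(match_cues(tk_adj, core)), 0)
})

test_that("deactivation flags 'not only' but leaves other cues active", {
  lex <- load_lexicon("c40")
  run <- function(words, lemmas, pos)
    apply_deactivation(match_cues(make_tokens(words, lemmas, pos), lex),
                       make_tokens(words, lemmas, pos))
  m1 <- run(c("activates", "not", "only", "IL-2", "but", "also", "IL-4"),
            c("activate", "not", "only", "IL-2", "but", "also", "IL-4"),
            c("VBZ", "RB", "RB", "NNP", "CC", "RB", "NNP"))
  expect_true(m1$deactivated[m1$display == "not"])
  m2 <- run(c("is", "not", "required", "for"),
            c("be", "not", "require", "for"),
            c("VBZ", "RB", "VBN", "IN"))
  expect_false(any(m2$deactivated))
  # "no evidence" stays active: scope-annotation deactivators for "no" do
  # not transfer to event-level polarity
  m3 <- run(c("no", "evidence", "that", "STAT1", "binds"),
            c("no", "evidence", "that", "STAT1", "bind"),
            c("DT", "NN", "IN", "NNP", "VBZ"))
  expect_false(m3$deactivated[m3$display == "no"])
  # flagging never adds or removes matches
  expect_equal(nrow(m1), nrow(match_cues(make_tokens(
    c("activates", "not", "only", "IL-2", "but", "also", "IL-4"),
    c("activate", "not", "only", "IL-2", "but", "also", "IL-4"),
    c("VBZ", "RB", "RB", "NNP", "CC", "RB", "NNP")), lex)))
})

test_that("matching agrees with the exhaustive n-gram oracle", {
  set.seed(401)
  lexs <- list(load_lexicon("c40"), load_lexicon("cBioScope"),
               load_lexicon("cCore"))
  for (i in 1:150) {
    tk <- random_cue_sentence()
    for (lex in lexs)
      expect_identical(match_cues(tk, lex), oracle_match_cues(tk, lex),
                       info = paste(tk$text, collapse = " "))
  }
})

test_that("core-list matches are a subset of combined-list matches", {
  set.seed(402)
  c40 <- load_lexicon("c40"); core <- load_lexicon("cCore")
  for (i in 1:60) {
    tk <- random_cue_sentence()
    m_core <- match_cues(tk, core); m_40 <- match_cues(tk, c40)
    if (nrow(m_core))
      for (j in seq_len(nrow(m_core)))
        expect_true(any(m_40$first == m_core$first[j] &
                        m_40$last == m_core$last[j]))
  }
})
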