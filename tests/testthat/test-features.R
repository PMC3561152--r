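fixture_cues <- function(fix, lexicon = "c40") {
  lex <- load_lexicon(lexicon)
  apply_deactivation(match_cues(fix$parse$tokens, lex), fix$parse$tokens)
}

test_that("cue selection takes the nearest active cue, leftmost on ties", {
  fix <- fig_negated_trigger_fixture()
  cues <- fixture_cues(fix)
  ev <- fix$doc$events[["E2"]]
  sel <- select_cue(cues, ev, fix$parse)
  expect_equal(sel$display, "not")
  # two cues at different distances: the closer one wins
  cues2 <- rbind(cues, data.frame(display = "never", first = 9L, last = 9L,
                                  deactivated = FALSE))
  expect_equal(select_cue(cues2, ev, fix$parse)$display, "not")
  # only a deactivated match present -> no cue
  cues3 <- cues; cues3$deactivated <- TRUE
  expect_null(select_cue(cues3, ev, fix$parse))
})

test_that("the negated-trigger fixture extracts the expected features", {
  fix <- fig_negated_trigger_fixture()
  cues <- fixture_cues(fix)
  f <- extract_features(fix$doc$events[["E2"]], fix$parse, cues, fix$doc)
  expect_true(f$cue_present)
  expect_equal(f$cue_id, "not")
  expect_true(f$cue_precedes_trigger)
  expect_equal(f$dist_cue_trigger, 1L)
  expect_false(f$cue_in_trigger)
  expect_true(f$is_complex)
  expect_true(f$dep_direct_cue_trigger)
  expect_equal(f$dep_chainlen_cue_trigger, 1L)
  expect_true(f$scope_has_trigger)
  expect_equal(f$event_type, "regulation")
  expect_equal(f$roles_present, "cause+theme")
  expect_equal(f$polarity, "negated")
  # the nested inner event is positive and simple
  f1 <- extract_features(fix$doc$events[["E1"]], fix$parse, cues, fix$doc)
  expect_false(f1$is_complex)
  expect_equal(f1$polarity, "positive")
})

test_that("a cue-free sentence yields the full sentinel contract", {
  fix <- fig_negated_trigger_fixture()
  empty_cues <- fixture_cues(fix)[0, ]
  f <- extract_features(fix$doc$events[["E2"]], fix$parse, empty_cues,
                        fix$doc)
  expect_false(f$cue_present)
  expect_equal(f$cue_id, "NONE")
  expect_equal(f$dist_cue_trigger, -1L)
  expect_equal(f$dist_cue_location, -1L)
  expect_equal(f$dep_chainlen_cue_trigger, -1L)
  expect_equal(f$dep_first_label_cue_trigger, "NONE")
  for (nm in names(FEATURE_SPEC)[FEATURE_SPEC == "bool"])
    if (nm != "is_complex") expect_false(f[[nm]], label = nm)
})

test_that("feature vectors are complete, consistent and deterministic", {
  corp <- generate_corpus(generator_config(n_sentences = 250, seed = 21))
  rows <- featurize_corpus(corp, "c40")
  expect_true(all(names(FEATURE_SPEC) %in% names(rows)))
  expect_false(anyNA(rows[names(FEATURE_SPEC)]))
  # sentinel consistency
  nocue <- rows[!rows$cue_present, ]
  expect_true(all(nocue$cue_id == "NONE"))
  expect_true(all(nocue$dist_cue_trigger == -1L))
  expect_true(all(!nocue$s_command_cue_trigger))
  expect_true(all(!nocue$scope_has_trigger))
  # cue in trigger implies zero distance
  expect_true(all(rows$dist_cue_trigger[rows$cue_in_trigger] == 0L))
  # direct dependency implies chain length one and connectivity
  dd <- rows[rows$dep_direct_cue_trigger, ]
  expect_true(all(dd$dep_chainlen_cue_trigger == 1L))
  expect_true(all(dd$dep_connected_cue_trigger))
  # determinism
  rows2 <- featurize_corpus(corp, "c40")
  expect_identical(rows, rows2)
})

test_that("scope features agree with direct range membership", {
  corp <- generate_corpus(generator_config(n_sentences = 120, seed = 23))
  lex <- load_lexicon("c40")
  bk <- corpus_backend(corp)
  checked <- 0L
  for (doc in corp$documents) {
    for (ev in doc$events) {
      s <- event_sentence(ev, doc)
      stext <- substr(doc$text, doc$sentences$start[s] + 1,
                      doc$sentences$end[s])
      parse <- parse_sentence(stext, bk)
      delta <- doc$sentences$start[s]
      parse$tokens$start <- parse$tokens$start + delta
      parse$tokens$end <- parse$tokens$end + delta
      cues <- apply_deactivation(match_cues(parse$tokens, lex), parse$tokens)
      f <- extract_features(ev, parse, cues, doc)
      sel <- select_cue(cues, ev, parse)
      if (is.null(sel)) next
      sc <- cue_scope(sel, parse)
      trig <- which(parse$tokens$start < ev$trigger$end &
                    ev$trigger$start < parse$tokens$end)
      th <- span_head(min(trig), max(trig), parse)
      expect_equal(f$scope_has_trigger, th >= sc[1] && th <= sc[2])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("one-hot encoding is schema-stable and invertible", {
  corp <- generate_corpus(generator_config(n_sentences = 200, seed = 25))
  rows <- featurize_corpus(corp, "c40")
  v <- vectorize(rows)
  expect_equal(nrow(v$x), nrow(rows))
  # identical feature rows encode identically
  same <- which(duplicated(rows[names(FEATURE_SPEC)]) |
                duplicated(rows[names(FEATURE_SPEC)], fromLast = TRUE))
  expect_gt(length(same), 1)
  # schema invariant under row order
  perm <- sample(nrow(rows))
  v2 <- vectorize(rows[perm, ])
  expect_identical(v$schema, v2$schema)
  expect_identical(colnames(v$x), colnames(v2$x))
  expect_equal(v$x[perm, ], v2$x, ignore_attr = TRUE)
  # encode/decode round-trip
  for (i in sample(nrow(rows), 25)) {
    dec <- unvectorize_row(v$x[i, ], v$schema)
    orig <- rows[i, names(FEATURE_SPEC)]
    rownames(orig) <- NULL
    expect_identical(dec, orig)
  }
  # missing columns raise a schema error
  expect_error(vectorize(rows[, 1:5]), "schema error")
})
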