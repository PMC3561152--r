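toy_separable <- function(n = 60, seed = 11) {
  set.seed(seed)
  y <- factor(rep(c("positive", "negated"), each = n / 2),
              levels = c("positive", "negated"))
  x <- cbind(signal = as.integer(y == "negated"),
             noise1 = sample(0:1, n, replace = TRUE),
             noise2 = sample(0:3, n, replace = TRUE))
  list(x = x, y = y)
}

test_that("precision/recall/F obey their bounds and conventions", {
  expect_equal(prf(c(tp = 0, fp = 0, fn = 0)),
               list(precision = 0, recall = 0, f_score = 0))
  set.seed(3)
  for (i in 1:50) {
    cts <- c(tp = sample(0:20, 1), fp = sample(0:20, 1),
             fn = sample(0:20, 1))
    m <- prf(cts)
    expect_gte(m$precision, 0); expect_lte(m$precision, 1)
    expect_gte(m$recall, 0); expect_lte(m$recall, 1)
    expect_gte(m$f_score, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f_score, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("micro average pools counts rather than averaging metrics", {
  r1 <- list(counts = c(tp = 10, fp = 2, fn = 5))
  expect_equal(micro_average(list(r1)), prf(r1$counts))
  expect_equal(micro_average(list(r1, r1)), prf(r1$counts))
  set.seed(8)
  for (i in 1:25) {
    reps <- lapply(1:3, function(j)
      list(counts = c(tp = sample(0:30, 1), fp = sample(0:30, 1),
                      fn = sample(0:30, 1))))
    pooled <- Reduce(`+`, lapply(reps, `[[`, "counts"))
    expect_equal(micro_average(reps), prf(pooled))
    # and differs in general from the mean of the metrics (when defined)
  }
})

test_that("every algorithm separates a separable training set", {
  toy <- toy_separable()
  for (algo in c("random_forest", "decision_tree", "logistic_regression",
                 "naive_bayes", "svm_poly", "nearest_neighbor_1")) {
    m <- polarity_model(toy$x, toy$y, model_spec(algo, seed = 2))
    pred <- predict(m, toy$x)
    cts <- c(tp = sum(pred == "negated" & toy$y == "negated"),
             fp = sum(pred == "negated" & toy$y == "positive"),
             fn = sum(pred == "positive" & toy$y == "negated"))
    expect_equal(prf(cts)$f_score, 1.0, info = algo)
  }
  expect_error(polarity_model(toy$x, factor(rep("positive", 60),
                                            levels = c("positive", "negated")),
                              model_spec()),
               "single class")
})

test_that("seeded fits give identical predictions across runs", {
  corp <- generate_corpus(generator_config(n_sentences = 250, seed = 17))
  v <- vectorize(featurize_corpus(corp, "c40"))
  for (algo in c("random_forest", "decision_tree", "logistic_regression")) {
    m1 <- polarity_model(v$x, v$y, model_spec(algo, seed = 99))
    m2 <- polarity_model(v$x, v$y, model_spec(algo, seed = 99))
    expect_identical(predict(m1, v$x), predict(m2, v$x), info = algo)
  }
})

test_that("cross-validation partitions rows exactly once with even folds", {
  toy <- toy_separable(n = 94, seed = 5)
  y <- toy$y
  fold <- negev:::stratified_folds(y, 10L, seed = 4)
  expect_length(fold, length(y))
  expect_setequal(unique(fold), 1:10)
  for (cls in levels(y)) {
    sizes <- table(fold[y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  ev <- cross_validate(toy$x, toy$y, model_spec("decision_tree", seed = 1),
                       k = 10)
  expect_equal(unname(colSums(as.matrix(ev$folds[, c("tp", "fp", "fn", "tn")]))),
               unname(ev$counts))
  expect_equal(sum(ev$counts), length(y))   # every row tested exactly once
  expect_equal(ev$f_score, 1.0)             # separable data
})

test_that("label permutation drops performance to chance", {
  corp <- generate_corpus(generator_config(n_sentences = 500, seed = 19,
                                           negation_rate = 0.15))
  v <- vectorize(featurize_corpus(corp, "c40"))
  set.seed(55)
  y_perm <- sample(v$y)
  ev <- suppressWarnings(
    cross_validate(v$x, y_perm, model_spec("random_forest", seed = 7), k = 10))
  base <- mean(y_perm == "negated")
  expect_lte(ev$f_score, base + 0.2)
})

test_that("the cue-list experiment reflects lexicon coverage", {
  # negations planted only via "fail": a list lacking that cue loses recall
  fail_lex <- tempfile(fileext = ".txt")
  writeLines("fail", fail_lex)
  cfg2 <- generator_config(n_sentences = 700, seed = 29,
                           type_mix = c(inherent = 0, trigger = 1,
                                        participant = 0, attribute = 0,
                                        contrast = 0),
                           cue_inventory = fail_lex)
  corp2 <- generate_corpus(cfg2)
  res <- run_cue_list_experiment(corp2, c("c40", "cBioInfer"),
                                 model_spec("random_forest", seed = 3),
                                 k = 10)
  r40 <- res$recall[res$lexicon == "c40"]
  rbi <- res$recall[res$lexicon == "cBioInfer"]
  expect_gt(r40, rbi)   # cBioInfer has no "fail" cue
})

test_that("split experiments assign classes and micro-average correctly", {
  corp <- generate_corpus(generator_config(n_sentences = 600, seed = 37))
  res <- suppressWarnings(
    run_split_experiment(corp, "two_way", spec = model_spec(seed = 2)))
  expect_setequal(names(res$sizes), c("simple", "complex"))
  # class sizes match the generator's bookkeeping
  expect_equal(unname(res$sizes["complex"]), sum(corp$gold$complex))
  expect_equal(unname(res$sizes["simple"]), sum(!corp$gold$complex))
  # micro average equals prf of pooled class counts
  pooled <- Reduce(`+`, lapply(res$per_class, `[[`, "counts"))
  expect_equal(res$micro, prf(pooled))
  res3 <- suppressWarnings(
    run_split_experiment(corp, "three_way", spec = model_spec(seed = 2)))
  expect_true(all(names(res3$sizes) %in% c("class1", "class2", "class3")))
})

test_that("gold splits are disjoint, exhaustive and stratified", {
  corp <- generate_corpus(generator_config(n_sentences = 800, seed = 41))
  sp <- gold_split(corp$gold, 0.5, seed = 6)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), corp$gold$event_id)
  expect_lte(abs(length(sp$train) - length(sp$test)), 2)
  rate <- mean(corp$gold$polarity == "negated")
  for (ids in list(sp$train, sp$test)) {
    r <- mean(corp$gold$polarity[corp$gold$event_id %in% ids] == "negated")
    expect_lt(abs(r - rate), 0.02 + 2 / sqrt(length(ids)))
  }
})
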