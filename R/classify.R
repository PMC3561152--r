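# ---------------------------------------------------------------------------
# Polarity classification and evaluation
#
# The positive class for precision/recall/F is "negated" throughout.
# ---------------------------------------------------------------------------

ALGORITHMS <- c("random_forest", "decision_tree", "logistic_regression",
                "naive_bayes", "svm_poly", "nearest_neighbor_1")

#' Model specification
#'
#' Hyperparameters default to the study settings: random forest with 10
#' trees and `floor(log2(N + 1))` candidate features per split (N = number
#' of columns); a pruned decision tree requiring at least 2 instances per
#' leaf; a polynomial-kernel SVM with complexity constant 1 and
#' range-normalised attributes; a 1-nearest-neighbour classifier on
#' normalised Euclidean distance; Gaussian naive Bayes; plain logistic
#' regression.
#'
#' @param algorithm One of `r paste0('"', ALGORITHMS, '"', collapse = ", ")`.
#' @param seed Integer seed, always recorded; seeded algorithms are
#'   reproducible given it.
#' @param ... Hyperparameter overrides (`ntree`, `mtry`, `minbucket`, `cp`,
#'   `cost`, `degree`).
#' @return An object of class `"negev_spec"`.
#' @export
model_spec <- function(algorithm = "random_forest", seed = 1L, ...) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  defaults <- switch(algorithm,
    random_forest = list(ntree = 10L, mtry = NULL),  # NULL -> floor(log2(N+1))
    decision_tree = list(minbucket = 2L, cp = 0.01),
    svm_poly = list(cost = 1, degree = 1L),
    list())
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 hyperparams = hp),
            class = "negev_spec")
}

#' Precision, recall and F-score from confusion counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F = 2PR / (P + R)`; any
#' 0/0 yields 0 by convention.
#'
#' @param counts Named vector or list with `tp`, `fp`, `fn`.
#' @return `list(precision, recall, f_score)` as fractions in `[0, 1]`.
#' @export
prf <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = p, recall = r, f_score = f_score(p, r))
}

#' Harmonic mean of precision and recall
#' @param precision,recall Fractions (or percentages, consistently).
#' @return The F-score on the same scale; 0 when both inputs are 0.
#' @export
f_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Micro-averaged precision/recall/F over several evaluation reports
#'
#' Raw tp/fp/fn counts are pooled across reports before computing the
#' metrics (not a mean of per-report metrics).
#'
#' @param reports List of evaluation reports (see [cross_validate()]) or of
#'   count vectors.
#' @return `list(precision, recall, f_score)`.
#' @export
micro_average <- function(reports) {
  pool <- c(tp = 0, fp = 0, fn = 0)
  for (r in reports) {
    cts <- if (is.list(r) && !is.null(r$counts)) r$counts else r
    pool <- pool + c(tp = cts[["tp"]], fp = cts[["fp"]], fn = cts[["fn"]])
  }
  prf(pool)
}

range_normalize <- function(x, fit = NULL) {
  if (is.null(fit)) {
    mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
    fit <- list(min = mins, range = pmax(maxs - mins, 1e-12))
  }
  xn <- sweep(sweep(x, 2, fit$min), 2, fit$range, "/")
  list(x = xn, fit = fit)
}

#' Fit a polarity classifier
#'
#' @param x Design matrix from [vectorize()].
#' @param y Factor with levels `positive`, `negated` (at least one example
#'   of each class).
#' @param spec A [model_spec()].
#' @return An object of class `"negev_model"` with a
#'   [predict.negev_model()] method returning one label per row.
#' @export
polarity_model <- function(x, y, spec = model_spec()) {
  stopifnot(inherits(spec, "negev_spec"))
  y <- factor(y, levels = c("positive", "negated"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training error: y contains a single class")
  set.seed(spec$seed)
  hp <- spec$hyperparams
  fit <- switch(spec$algorithm,
    random_forest = {
      mtry <- if (is.null(hp$mtry)) max(1L, floor(log2(ncol(x) + 1)))
              else hp$mtry
      randomForest::randomForest(x = x, y = y, ntree = hp$ntree, mtry = mtry)
    },
    decision_tree = {
      df <- as.data.frame(x); df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minbucket = hp$minbucket,
                                                  cp = hp$cp, xval = 0))
    },
    logistic_regression = {
      df <- as.data.frame(x); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    naive_bayes = {
      e1071::naiveBayes(x = as.data.frame(x), y = y)
    },
    svm_poly = {
      nrm <- range_normalize(x)
      list(norm = nrm$fit,
           svm = e1071::svm(x = nrm$x, y = y, kernel = "polynomial",
                            degree = hp$degree, cost = hp$cost,
                            coef0 = 1, scale = FALSE))
    },
    nearest_neighbor_1 = {
      nrm <- range_normalize(x)
      list(norm = nrm$fit, x = nrm$x, y = y)
    })
  structure(list(algorithm = spec$algorithm, spec = spec, fit = fit,
                 n = nrow(x), p = ncol(x), columns = colnames(x)),
            class = "negev_model")
}

#' Predict event polarity
#'
#' @param object A fitted [polarity_model()].
#' @param newdata Design matrix with the same columns as at training.
#' @param ... Unused.
#' @return Factor of `positive` / `negated`, one label per row.
#' @export
predict.negev_model <- function(object, newdata, ...) {
  x <- newdata[, object$columns, drop = FALSE]
  lv <- c("positive", "negated")
  out <- switch(object$algorithm,
    random_forest = predict(object$fit, x),
    decision_tree = {
      cls <- predict(object$fit, as.data.frame(x), type = "class")
      cls
    },
    logistic_regression = {
      pr <- suppressWarnings(
        predict(object$fit, as.data.frame(x), type = "response"))
      factor(ifelse(pr > 0.5, "negated", "positive"), levels = lv)
    },
    naive_bayes = {
      predict(object$fit, as.data.frame(x), threshold = 0.001)
    },
    svm_poly = {
      xn <- range_normalize(x, object$fit$norm)$x
      predict(object$fit$svm, xn)
    },
    nearest_neighbor_1 = {
      xn <- range_normalize(x, object$fit$norm)$x
      class::knn1(object$fit$x, xn, object$fit$y)
    })
  factor(as.character(out), levels = lv)
}

#' @export
print.negev_model <- function(x, ...) {
  cat("<negev_model> ", x$algorithm, " fitted on ", x$n, " events x ",
      x$p, " encoded features (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.negev_model <- function(object, ...) {
  print(object)
  cat("hyperparameters:\n")
  utils::str(object$spec$hyperparams, give.attr = FALSE)
  invisible(object)
}

confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == "negated" & truth == "negated"),
    fp = sum(pred == "negated" & truth == "positive"),
    fn = sum(pred == "positive" & truth == "negated"),
    tn = sum(pred == "positive" & truth == "positive"))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) > 0L && length(idx) < k)
      warning("class '", cls, "' has fewer members (", length(idx),
              ") than folds (", k, "); stratification is best-effort")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Folds are drawn from a seeded, polarity-stratified shuffle; every row is
#' tested exactly once; fold sizes differ by at most one within each class.
#' Aggregate counts are the sum over folds.
#'
#' @param x Design matrix.
#' @param y Polarity factor.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param fold_seed Seed for fold construction (default: `spec$seed`).
#' @return An object of class `"negev_eval"`: per-fold counts, pooled
#'   counts, `precision`, `recall`, `f_score` (fractions), the spec and
#'   fold seed.
#' @export
cross_validate <- function(x, y, spec = model_spec(), k = 10L,
                           fold_seed = spec$seed) {
  y <- factor(y, levels = c("positive", "negated"))
  stopifnot(nrow(x) >= k, nlevels(droplevels(y)) == 2L)
  fold <- stratified_folds(y, k, fold_seed)
  per_fold <- matrix(0, nrow = k, ncol = 4,
                     dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    model <- polarity_model(x[tr, , drop = FALSE], y[tr], spec)
    pred <- predict(model, x[te, , drop = FALSE])
    per_fold[f, ] <- confusion_counts(pred, y[te])
  }
  counts <- colSums(per_fold)
  structure(c(list(folds = as.data.frame(cbind(fold = seq_len(k), per_fold)),
                   counts = counts, spec = spec, fold_seed = fold_seed),
              prf(counts)),
            class = "negev_eval")
}

#' @export
print.negev_eval <- function(x, ...) {
  cat("<negev_eval> ", x$spec$algorithm, ", ", nrow(x$folds),
      "-fold CV\n", sep = "")
  cat(sprintf("  P = %.1f%%  R = %.1f%%  F = %.1f%%   (tp %d, fp %d, fn %d)\n",
              100 * x$precision, 100 * x$recall, 100 * x$f_score,
              x$counts[["tp"]], x$counts[["fp"]], x$counts[["fn"]]))
  invisible(x)
}

#' Lexical baseline: predict negated iff any active cue is present
#'
#' The cue-presence-only baseline that event-level classification must
#' beat: a sentence containing a negation cue need not contain any negated
#' event, and vice versa.
#'
#' @param rows Feature data frame from [featurize_corpus()].
#' @return Factor of predictions.
#' @export
lexical_baseline <- function(rows) {
  factor(ifelse(rows$cue_present, "negated", "positive"),
         levels = c("positive", "negated"))
}

#' Cue-list comparison experiment
#'
#' Re-featurizes the corpus once per lexicon and cross-validates a fixed
#' model (default: the random forest spec) on each, reporting one
#' P/R/F row per cue list.
#'
#' @param corpus A `"negev_corpus"`.
#' @param lexicons Character vector of lexicon names.
#' @param spec A [model_spec()].
#' @param k Folds.
#' @param backend Optional parse backend (default: corpus fixtures).
#' @return Data frame `lexicon`, `precision`, `recall`, `f_score`
#'   (fractions) with the reports as attribute `"reports"`.
#' @export
run_cue_list_experiment <- function(corpus, lexicons = LEXICON_NAMES,
                                    spec = model_spec(), k = 10L,
                                    backend = NULL) {
  reports <- list()
  for (lx in lexicons) {
    rows <- featurize_corpus(corpus, lx, backend)
    v <- vectorize(rows)
    reports[[lx]] <- cross_validate(v$x, v$y, spec, k)
  }
  out <- data.frame(lexicon = lexicons,
                    precision = vapply(reports, `[[`, 0, "precision"),
                    recall = vapply(reports, `[[`, 0, "recall"),
                    f_score = vapply(reports, `[[`, 0, "f_score"),
                    row.names = NULL)
  attr(out, "reports") <- reports
  out
}

THREE_WAY_CLASSES <- list(
  class1 = c("localization", "transcription", "protein_catabolism",
             "gene_expression", "phosphorylation"),
  class2 = "binding",
  class3 = c("regulation", "positive_regulation", "negative_regulation"))

#' Event-type splitting experiment
#'
#' `three_way` partitions events into Class-1 (localization, transcription,
#' protein_catabolism, gene_expression, phosphorylation), Class-2 (binding)
#' and Class-3 (the regulation types); `two_way` splits by complexity
#' status (simple vs complex).  A classifier is trained and tested per
#' class and the per-class counts are micro-averaged.
#'
#' @param corpus A `"negev_corpus"`.
#' @param mode `"three_way"` or `"two_way"`.
#' @param lexicon Lexicon name or object for featurization.
#' @param spec A [model_spec()].
#' @param k Folds.
#' @return `list(per_class = named list of reports or NULL for classes
#'   lacking both polarities, sizes = events per class, micro =
#'   micro-averaged P/R/F)`.
#' @export
run_split_experiment <- function(corpus, mode = c("three_way", "two_way"),
                                 lexicon = "c40", spec = model_spec(),
                                 k = 10L) {
  mode <- match.arg(mode)
  rows <- featurize_corpus(corpus, lexicon)
  cls <- if (mode == "two_way") {
    ifelse(rows$is_complex, "complex", "simple")
  } else {
    known <- unlist(THREE_WAY_CLASSES)
    bad <- setdiff(unique(rows$event_type), known)
    if (length(bad))
      stop("assignment error: event types outside the three-way classes: ",
           paste(bad, collapse = ", "))
    vapply(rows$event_type, function(t) {
      names(THREE_WAY_CLASSES)[vapply(THREE_WAY_CLASSES,
                                      function(v) t %in% v, logical(1))]
    }, "")
  }
  reports <- list(); counts <- list(); sizes <- table(cls)
  for (cl in sort(unique(cls))) {
    sub <- rows[cls == cl, , drop = FALSE]
    v <- vectorize(sub)
    if (nlevels(droplevels(v$y)) < 2L || nrow(sub) < k) {
      warning("class '", cl, "' lacks both polarities (or has < k events); ",
              "scoring the all-positive prediction")
      reports[[cl]] <- NULL
      counts[[cl]] <- c(tp = 0, fp = 0,
                        fn = sum(v$y == "negated"),
                        tn = sum(v$y == "positive"))
    } else {
      reports[[cl]] <- cross_validate(v$x, v$y, spec, k)
      counts[[cl]] <- reports[[cl]]$counts
    }
  }
  list(per_class = reports, sizes = sizes, micro = micro_average(counts))
}

#' Stratified train/test split of gold records
#'
#' @param gold Gold record data frame (columns `event_id`, `polarity`).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return `list(train = ids, test = ids)`; disjoint, exhaustive,
#'   stratified by polarity.
#' @export
gold_split <- function(gold, train_fraction = 0.5, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  train <- character()
  for (cls in unique(gold$polarity)) {
    ids <- gold$event_id[gold$polarity == cls]
    if (length(ids) < 2L)
      warning("polarity class '", cls, "' has fewer than 2 events; ",
              "split is best-effort")
    n_tr <- round(length(ids) * train_fraction)
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, test = setdiff(gold$event_id, train))
}
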