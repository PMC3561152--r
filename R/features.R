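# ---------------------------------------------------------------------------
# Feature engineering
#
# One (event, parse, cue matches) triple maps to a fixed-schema feature
# vector covering six families: syntactic (POS of event anchors), semantic
# (event type, roles, participant types, complexity), lexical (cue presence
# and identity, deactivators), lexico-semantic (surface distances and
# ordering between cue and trigger/location), dependency (existence, type
# and length of dependency chains cue<->trigger and cue<->location) and
# constituency (S/VP/NP-command relations and cue-scope membership).
# Missing values always use declared sentinels (NONE / -1 / FALSE), never
# absent keys, so every event yields the identical feature name set.
# ---------------------------------------------------------------------------

#' Feature schema
#'
#' Named character vector mapping each feature name to its kind:
#' `"cat"` (categorical, sentinel `"NONE"`), `"bool"` (sentinel `FALSE`) or
#' `"int"` (sentinel `-1`).
#' @export
FEATURE_SPEC <- c(
  # syntactic
  pos_trigger = "cat", pos_theme = "cat", pos_cause = "cat", pos_cue = "cat",
  # semantic
  event_type = "cat", roles_present = "cat", participant_types = "cat",
  is_complex = "bool",
  # lexical
  cue_present = "bool", cue_id = "cat", deactivator_present = "bool",
  deactivator_relpos = "cat",
  # lexico-semantic
  dist_cue_trigger = "int", dist_cue_location = "int",
  cue_in_trigger = "bool", cue_precedes_trigger = "bool",
  # dependency
  dep_direct_cue_trigger = "bool", dep_connected_cue_trigger = "bool",
  dep_first_label_cue_trigger = "cat", dep_chainlen_cue_trigger = "int",
  dep_direct_cue_location = "bool", dep_connected_cue_location = "bool",
  dep_first_label_cue_location = "cat", dep_chainlen_cue_location = "int",
  # constituency
  s_command_cue_trigger = "bool", vp_command_cue_trigger = "bool",
  np_command_cue_trigger = "bool", s_command_cue_location = "bool",
  vp_command_cue_location = "bool", np_command_cue_location = "bool",
  scope_has_trigger = "bool", scope_has_participant = "bool",
  scope_has_location = "bool")

# Map a document-absolute character span to the 1-based token indices of a
# parse whose token table carries absolute offsets.
span_token_range <- function(span, parse) {
  t <- parse$tokens
  hits <- which(t$start < span$end & span$start < t$end)
  if (length(hits) == 0L)
    stop("alignment error: span [", span$start, ", ", span$end,
         ") '", span$text, "' maps to no tokens")
  range(hits)
}

span_head_token <- function(span, parse) {
  r <- span_token_range(span, parse)
  span_head(r[1], r[2], parse)
}

#' Select the cue a feature vector is computed against
#'
#' Among the non-deactivated cue matches of the event's sentence, the one
#' whose tokens lie closest to the event-trigger head is selected; ties go
#' to the leftmost match.  Returns `NULL` when no active cue exists (a
#' sentence whose only matches are deactivated yields no cue).
#'
#' @param cues [match_cues()] output (after [apply_deactivation()]).
#' @param event The [bio_event()].
#' @param parse The sentence [parse_result()].
#' @return One row of `cues`, or `NULL`.
#' @export
select_cue <- function(cues, event, parse) {
  active <- cues[!cues$deactivated, , drop = FALSE]
  if (nrow(active) == 0L) return(NULL)
  trig <- span_head_token(event$trigger, parse)
  dist <- vapply(seq_len(nrow(active)), function(i)
    min(abs(seq(active$first[i], active$last[i]) - trig)), 0)
  active[order(dist, active$first)[1L], , drop = FALSE]
}

participant_span <- function(p, doc) {
  if (p$ref_type == "entity") doc$entities[[p$ref]]$span
  else doc$events[[p$ref]]$trigger   # nested event: trigger stands in
}

first_role_span <- function(event, role, doc) {
  for (p in event$participants) if (p$role == role)
    return(participant_span(p, doc))
  NULL
}

#' Extract the feature vector for one event
#'
#' Cue-dependent features are computed against the cue chosen by
#' [select_cue()]; the deactivator features are computed from any
#' deactivated match in the sentence regardless of cue selection.  Surface
#' distances are measured in tokens between head tokens; `-1` is the
#' sentinel for "no cue" / "no location".
#'
#' @param event A [bio_event()] aligned to the parsed sentence.
#' @param parse The sentence [parse_result()] (token offsets must be
#'   document-absolute).
#' @param cues [match_cues()] + [apply_deactivation()] output for the
#'   sentence.
#' @param doc The containing [document()] (resolves participant spans).
#' @return A one-row data frame with exactly the [FEATURE_SPEC] columns,
#'   preceded by `event_id` and followed by `polarity`.
#' @export
extract_features <- function(event, parse, cues, doc) {
  f <- list()
  sentinel <- function(kind) switch(kind, cat = "NONE", bool = FALSE, int = -1L)
  for (nm in names(FEATURE_SPEC)) f[[nm]] <- sentinel(FEATURE_SPEC[[nm]])

  trig_head <- span_head_token(event$trigger, parse)
  f$pos_trigger <- parse$tokens$pos[trig_head]
  theme_span <- first_role_span(event, "theme", doc)
  if (!is.null(theme_span))
    f$pos_theme <- parse$tokens$pos[span_head_token(theme_span, parse)]
  cause_span <- first_role_span(event, "cause", doc)
  if (!is.null(cause_span))
    f$pos_cause <- parse$tokens$pos[span_head_token(cause_span, parse)]

  f$event_type <- event$type
  roles <- sort(unique(vapply(event$participants, `[[`, "", "role")))
  f$roles_present <- if (length(roles)) paste(roles, collapse = "+") else "NONE"
  ptypes <- sort(unique(vapply(event$participants, function(p)
    if (p$ref_type == "event") "event" else doc$entities[[p$ref]]$type, "")))
  f$participant_types <-
    if (length(ptypes)) paste(ptypes, collapse = "+") else "NONE"
  f$is_complex <- is_complex(event)

  loc_head <- NA_integer_
  if (!is.na(event$location))
    loc_head <- span_head_token(doc$entities[[event$location]]$span, parse)

  deact <- cues[cues$deactivated, , drop = FALSE]
  f$deactivator_present <- nrow(deact) > 0L

  cue <- select_cue(cues, event, parse)
  if (!is.null(cue)) {
    cue_head <- span_head(cue$first, cue$last, parse)
    trig_range <- span_token_range(event$trigger, parse)

    f$cue_present <- TRUE
    f$cue_id <- cue$display
    f$pos_cue <- parse$tokens$pos[cue_head]
    f$cue_in_trigger <- cue$first >= trig_range[1] && cue$last <= trig_range[2]
    f$dist_cue_trigger <-
      if (f$cue_in_trigger) 0L else abs(cue_head - trig_head)
    f$cue_precedes_trigger <- cue_head < trig_head

    pt <- dep_path(cue_head, trig_head, parse)
    f$dep_connected_cue_trigger <- pt$exists && pt$length > 0L
    f$dep_direct_cue_trigger <- pt$direct
    if (f$dep_connected_cue_trigger) {
      f$dep_first_label_cue_trigger <- pt$labels[1L]
      f$dep_chainlen_cue_trigger <- pt$length
    }
    f$s_command_cue_trigger  <- cmd_safe(cue_head, trig_head, "S",  parse)
    f$vp_command_cue_trigger <- cmd_safe(cue_head, trig_head, "VP", parse)
    f$np_command_cue_trigger <- cmd_safe(cue_head, trig_head, "NP", parse)

    if (!is.na(loc_head)) {
      f$dist_cue_location <- abs(cue_head - loc_head)
      pl <- dep_path(cue_head, loc_head, parse)
      f$dep_connected_cue_location <- pl$exists && pl$length > 0L
      f$dep_direct_cue_location <- pl$direct
      if (f$dep_connected_cue_location) {
        f$dep_first_label_cue_location <- pl$labels[1L]
        f$dep_chainlen_cue_location <- pl$length
      }
      f$s_command_cue_location  <- cmd_safe(cue_head, loc_head, "S",  parse)
      f$vp_command_cue_location <- cmd_safe(cue_head, loc_head, "VP", parse)
      f$np_command_cue_location <- cmd_safe(cue_head, loc_head, "NP", parse)
    }

    scope <- cue_scope(cue, parse)
    in_scope <- function(tok) !is.na(tok) && tok >= scope[1] && tok <= scope[2]
    f$scope_has_trigger <- in_scope(trig_head)
    f$scope_has_location <- in_scope(loc_head)
    part_heads <- vapply(event$participants, function(p)
      span_head_token(participant_span(p, doc), parse), 0L)
    f$scope_has_participant <- any(vapply(part_heads, in_scope, logical(1)))

    if (f$deactivator_present)
      f$deactivator_relpos <-
        if (deact$last[1L] + 1L < cue_head) "before" else "after"
  } else if (f$deactivator_present) {
    f$deactivator_relpos <- "after"   # deactivator follows its own "not"
  }

  cbind(data.frame(event_id = event$id), as.data.frame(f),
        data.frame(polarity = event$polarity))
}

cmd_safe <- function(x, y, category, parse) {
  if (x == y) return(FALSE)
  commands(x, y, category, parse)
}

#' Feature table for a whole corpus
#'
#' Matches cues once per sentence, then extracts one feature row per event.
#'
#' @param corpus A `"negev_corpus"` (see [generate_corpus()]) or a list with
#'   `documents` and `parses`.
#' @param lexicon A [load_lexicon()] result (or a lexicon name).
#' @param backend Optional parse backend; defaults to the corpus's own
#'   fixture parses.
#' @return Data frame: `doc_id`, `event_id`, the [FEATURE_SPEC] columns,
#'   `polarity`.
#' @export
featurize_corpus <- function(corpus, lexicon = "c40", backend = NULL) {
  if (is.character(lexicon)) lexicon <- load_lexicon(lexicon)
  if (is.null(backend)) backend <- corpus_backend(corpus)
  rows <- vector("list", 1000L); nr <- 0L
  for (doc in corpus$documents) {
    sent_of <- vapply(doc$events, event_sentence, 0L, doc = doc)
    for (s in unique(sent_of)) {
      stext <- substr0(doc$text, doc$sentences$start[s], doc$sentences$end[s])
      parse <- parse_sentence(stext, backend)
      # fixture token offsets are sentence-relative; event spans are absolute
      delta <- doc$sentences$start[s]
      if (!is.null(parse$tokens$start) && delta != 0L) {
        parse$tokens$start <- parse$tokens$start + delta
        parse$tokens$end <- parse$tokens$end + delta
      }
      cues <- apply_deactivation(match_cues(parse$tokens, lexicon),
                                 parse$tokens)
      for (ev in doc$events[sent_of == s]) {
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- cbind(data.frame(doc_id = doc$doc_id),
                            extract_features(ev, parse, cues, doc))
      }
    }
  }
  do.call(rbind, rows[seq_len(nr)])
}

#' One-hot encode a feature table
#'
#' Categorical features are expanded to indicator columns with an explicit
#' `NONE` level; booleans and integers pass through.  The column schema is
#' deterministic — sorted feature names, sorted category levels — so the
#' same rows produce bit-identical matrices across runs and row orders.
#'
#' @param rows A feature data frame from [featurize_corpus()] /
#'   [extract_features()].
#' @param schema Optional schema from a previous call (to encode new rows
#'   into an existing design space; unseen levels map to all-zero blocks).
#' @return `list(x = design matrix, y = polarity factor or NULL,
#'   ids = event ids, schema = list(levels per categorical feature))`.
#' @export
vectorize <- function(rows, schema = NULL) {
  need <- names(FEATURE_SPEC)
  if (!all(need %in% names(rows)))
    stop("schema error: feature table is missing columns: ",
         paste(setdiff(need, names(rows)), collapse = ", "))
  feat_names <- sort(need)
  if (is.null(schema)) {
    schema <- list()
    for (nm in feat_names)
      if (FEATURE_SPEC[[nm]] == "cat")
        schema[[nm]] <- sort(unique(c("NONE", as.character(rows[[nm]]))))
  }
  cols <- list()
  for (nm in feat_names) {
    kind <- FEATURE_SPEC[[nm]]
    if (kind == "cat") {
      for (lv in schema[[nm]]) {
        cols[[paste0(nm, "=", lv)]] <-
          as.integer(as.character(rows[[nm]]) == lv)
      }
    } else {
      cols[[nm]] <- as.integer(rows[[nm]])
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  y <- if ("polarity" %in% names(rows))
    factor(rows$polarity, levels = c("positive", "negated")) else NULL
  ids <- if ("event_id" %in% names(rows)) rows$event_id else NULL
  list(x = x, y = y, ids = ids, schema = schema)
}

#' Decode one design-matrix row back into a feature vector
#'
#' Inverse of [vectorize()] for round-trip checking.
#'
#' @param xrow One row of the design matrix.
#' @param schema The schema returned by [vectorize()].
#' @return A one-row data frame with the [FEATURE_SPEC] columns.
#' @export
unvectorize_row <- function(xrow, schema) {
  out <- list()
  for (nm in sort(names(FEATURE_SPEC))) {
    kind <- FEATURE_SPEC[[nm]]
    if (kind == "cat") {
      hits <- schema[[nm]][vapply(schema[[nm]], function(lv)
        xrow[[paste0(nm, "=", lv)]] == 1L, logical(1))]
      out[[nm]] <- if (length(hits)) hits[1L] else "NONE"
    } else if (kind == "bool") {
      out[[nm]] <- as.logical(xrow[[nm]])
    } else {
      out[[nm]] <- as.integer(xrow[[nm]])
    }
  }
  as.data.frame(out)[names(FEATURE_SPEC)]
}
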