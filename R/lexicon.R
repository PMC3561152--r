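# ---------------------------------------------------------------------------
# Negation cue lexicons
#
# Four curated lists ship with the package: c40 (40 cues combined from
# published lists plus corpus analysis), cBioScope (28 cues from scope
# annotation of biomedical text), cBioInfer (25 cues annotated in a
# bio-relation corpus), and cCore (the most frequent cues observed across
# negated events; 19 entries).  Entries are citation-form lemmas, optionally
# POS-restricted ("lack (noun)" vs "lack (verb)"), and may span several
# tokens ("could not", "with the exception of").
# ---------------------------------------------------------------------------

LEXICON_NAMES <- c("c40", "cBioScope", "cBioInfer", "cCore")

#' Deactivators of the cue "not"
#'
#' When "not" is immediately followed by one of these words it ceases to act
#' as a negation cue (the pattern `not <deactivator>`).  Analogous
#' deactivation patterns proposed for "no" in scope-annotation work (e.g.
#' "no evidence of") are deliberately *not* applied: under event-level
#' annotation such constructions do trigger negated events.
#' @export
NOT_DEACTIVATORS <- c("clear", "evident", "known", "necessarily", "only")

parse_lexicon_lines <- function(lines, name) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "|", fixed = TRUE)[[1]]
    pos <- if (length(parts) == 2L) match.arg(parts[2], c("noun", "verb"))
           else NA_character_
    lemmas <- strsplit(tolower(parts[1]), " ", fixed = TRUE)[[1]]
    display <- if (is.na(pos)) parts[1] else paste0(parts[1], " (", pos, ")")
    list(lemmas = lemmas, pos = pos, display = display)
  })
  displays <- vapply(entries, `[[`, "", "display")
  if (anyDuplicated(displays))
    stop("duplicate lexicon entries in ", name, ": ",
         paste(displays[duplicated(displays)], collapse = ", "))
  structure(list(name = name, entries = entries), class = "negev_lexicon")
}

#' Load a packaged negation cue lexicon
#'
#' @param name One of `"c40"`, `"cBioScope"`, `"cBioInfer"`, `"cCore"`, or a
#'   path to a custom lexicon file (one entry per line, lemmas separated by
#'   spaces, optional `|noun` / `|verb` suffix restricting the entry's POS).
#' @return An object of class `"negev_lexicon"` with a list of entries.
#'   Note the published cCore list states size 20 but prints 19 elements;
#'   the packaged lexicon carries the 19 printed elements.
#' @export
load_lexicon <- function(name) {
  if (name %in% LEXICON_NAMES) {
    path <- system.file("extdata", "lexicons", paste0(name, ".txt"),
                        package = "negev", mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop("unknown lexicon '", name, "'; valid names: ",
         paste(LEXICON_NAMES, collapse = ", "),
         " (or a path to a lexicon file)")
  }
  parse_lexicon_lines(readLines(path, encoding = "UTF-8"),
                      if (name %in% LEXICON_NAMES) name else basename(name))
}

#' @export
print.negev_lexicon <- function(x, ...) {
  cat("<negev_lexicon> ", x$name, ": ", length(x$entries), " entries\n",
      sep = "")
  invisible(x)
}

pos_compatible <- function(pos_tag, constraint) {
  if (is.na(constraint)) return(TRUE)
  if (constraint == "noun") return(startsWith(pos_tag, "NN"))
  if (constraint == "verb") return(startsWith(pos_tag, "VB"))
  FALSE
}

#' Match negation cues in a tokenized sentence
#'
#' Matching is case-insensitive and lemma-based (an entry matches a token
#' whose lemma or lower-cased surface equals the entry lemma), so inflected
#' instances (fails/failed) match their citation form.  All maximal
#' non-overlapping matches are returned: entries are tried longest-first at
#' each position, left to right, so multi-word entries ("could not") take
#' precedence over their sub-spans ("not").  POS-restricted entries only
#' match tokens with a compatible tag.
#'
#' @param tokens Data frame with columns `text`, `lemma`, `pos` (one row per
#'   token, in sentence order).
#' @param lexicon A [load_lexicon()] result.
#' @return Data frame of matches, one row per cue occurrence: `display`
#'   (lexicon entry), `first`, `last` (1-based inclusive token indices),
#'   `deactivated` (all `FALSE`; see [apply_deactivation()]).
#' @export
match_cues <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "negev_lexicon"))
  empty <- data.frame(display = character(), first = integer(),
                      last = integer(), deactivated = logical())
  n <- nrow(tokens)
  if (is.null(n) || n == 0L) return(empty)
  lem <- tolower(tokens$lemma)
  surf <- tolower(tokens$text)
  ord <- order(-vapply(lexicon$entries, function(e) length(e$lemmas), 1L))
  entries <- lexicon$entries[ord]

  hit_at <- function(e, i) {
    k <- length(e$lemmas)
    if (i + k - 1L > n) return(FALSE)
    idx <- i:(i + k - 1L)
    ok <- all(lem[idx] == e$lemmas | surf[idx] == e$lemmas)
    ok && pos_compatible(tokens$pos[i + k - 1L], e$pos)
  }

  res <- empty
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (e in entries) {
      if (hit_at(e, i)) {
        res <- rbind(res, data.frame(display = e$display, first = i,
                                     last = i + length(e$lemmas) - 1L,
                                     deactivated = FALSE))
        i <- i + length(e$lemmas)
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  res
}

#' Flag deactivated cue matches
#'
#' A match on the cue "not" is flagged as deactivated iff the immediately
#' following token's lemma is one of [NOT_DEACTIVATORS].  Matches are never
#' removed, only flagged, because downstream features record the presence
#' and relative position of deactivators.  No deactivation pattern is
#' applied to "no"-constructions ("no evidence ..." remains an active cue).
#'
#' @param matches Output of [match_cues()] on the same `tokens`.
#' @param tokens The sentence token data frame.
#' @return `matches` with the `deactivated` column updated.
#' @export
apply_deactivation <- function(matches, tokens) {
  if (nrow(matches) == 0L) return(matches)
  lem <- tolower(tokens$lemma)
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    is_not <- m$first == m$last && lem[m$first] == "not"
    if (is_not && m$last < nrow(tokens) &&
        lem[m$last + 1L] %in% NOT_DEACTIVATORS)
      matches$deactivated[i] <- TRUE
  }
  matches
}
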