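#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Bio-event data model
#
# Character offsets are 0-based and half-open throughout ([start, end)), the
# de-facto convention of BioNLP-ST standoff annotation.  Token indices, by
# contrast, are 1-based inside the R API.
# ---------------------------------------------------------------------------

#' Construct a text span
#'
#' A span anchors an annotation (entity or event trigger) to the document
#' text by 0-based half-open character offsets.
#'
#' @param start,end Integer character offsets, `0 <= start < end`.
#' @param text Surface string; must equal the document substring at
#'   `[start, end)` (checked when the span is attached to a document).
#' @return An object of class `"negev_span"`.
#' @export
text_span <- function(start, end, text) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid span: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(start = start, end = end, text = as.character(text)),
            class = "negev_span")
}

#' Construct an entity annotation
#'
#' @param id Identifier, unique within the document (e.g. `"T1"`).
#' @param type Semantic type label (e.g. `"protein"`, `"operon"`).
#' @param span A [text_span()].
#' @return An object of class `"negev_entity"`.
#' @export
entity <- function(id, type, span) {
  stopifnot(inherits(span, "negev_span"))
  structure(list(id = as.character(id), type = as.character(type), span = span),
            class = "negev_entity")
}

#' Construct a bio-event
#'
#' A bio-event is a typed relation anchored to a trigger span, with
#' role-labelled participants that may be entities or other events (an event
#' with at least one event-valued participant is *complex*), an optional
#' location attribute, and a polarity: `"positive"` (asserted) or
#' `"negated"` (asserted not to occur).
#'
#' @param id Identifier (e.g. `"E1"`).
#' @param type Event type label (e.g. `"positive_regulation"`).
#' @param trigger A [text_span()] anchoring the event.
#' @param participants List of `list(role =, ref =, ref_type =)` where
#'   `ref` is an entity or event id and `ref_type` is `"entity"` or
#'   `"event"`.
#' @param location Entity id of the location attribute, or `NA`.
#' @param polarity `"positive"` or `"negated"`.
#' @return An object of class `"negev_event"`.
#' @export
bio_event <- function(id, type, trigger, participants = list(),
                      location = NA_character_, polarity = "positive") {
  stopifnot(inherits(trigger, "negev_span"))
  polarity <- match.arg(polarity, c("positive", "negated"))
  for (p in participants) {
    if (!all(c("role", "ref", "ref_type") %in% names(p)) ||
        !p$ref_type %in% c("entity", "event"))
      stop("each participant needs role, ref and ref_type ('entity'|'event')")
  }
  structure(list(id = as.character(id), type = as.character(type),
                 trigger = trigger, participants = participants,
                 location = as.character(location), polarity = polarity),
            class = "negev_event")
}

#' Is an event complex?
#'
#' An event is complex when one or more of its participants is itself a
#' bio-event (nested event structure).
#'
#' @param event A [bio_event()].
#' @return `TRUE` iff any participant has `ref_type == "event"`.
#' @export
is_complex <- function(event) {
  stopifnot(inherits(event, "negev_event"))
  any(vapply(event$participants, function(p) p$ref_type == "event", logical(1)))
}

#' Construct a document
#'
#' Sentence spans are taken from the parse backend (here: supplied or derived
#' by newline splitting); they must be non-overlapping and ordered, and every
#' entity and trigger span must fall inside exactly one sentence.  Events
#' whose participants straddle sentences are aligned to the sentence holding
#' their trigger.
#'
#' @param doc_id Document identifier.
#' @param text Full document text.
#' @param entities Named list of [entity()] objects (names = ids).
#' @param events Named list of [bio_event()] objects (names = ids).
#' @param sentences Data frame with columns `start`, `end` (0-based
#'   half-open); default: one sentence per newline-separated line.
#' @param modifications Data frame of M-records other than the polarity flag
#'   (columns `id`, `type`, `event_id`); parsed and preserved, ignored by the
#'   classifier.
#' @return An object of class `"negev_document"`.
#' @export
document <- function(doc_id, text, entities = list(), events = list(),
                     sentences = NULL, modifications = NULL) {
  if (is.null(sentences)) sentences <- sentence_spans_from_lines(text)
  if (is.null(modifications))
    modifications <- data.frame(id = character(), type = character(),
                                event_id = character())
  if (length(entities)) names(entities) <- vapply(entities, `[[`, "", "id")
  if (length(events))   names(events)   <- vapply(events, `[[`, "", "id")
  doc <- structure(list(doc_id = as.character(doc_id), text = text,
                        sentences = sentences, entities = entities,
                        events = events, modifications = modifications),
                   class = "negev_document")
  validate_document(doc)
  doc
}

sentence_spans_from_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) return(data.frame(start = integer(), end = integer()))
  ends <- cumsum(nchar(lines) + 1L) - 1L     # exclude the newline
  starts <- c(0L, utils::head(ends, -1L) + 1L)
  data.frame(start = starts, end = ends)
}

substr0 <- function(text, start, end) substr(text, start + 1L, end)

span_sentence <- function(span, sentences) {
  hit <- which(sentences$start <= span$start & span$end <= sentences$end)
  if (length(hit) != 1L)
    stop("span [", span$start, ", ", span$end,
         ") does not lie inside exactly one sentence")
  hit
}

#' Sentence index of an event
#'
#' Events are aligned to the sentence containing their trigger.
#'
#' @param event A [bio_event()].
#' @param doc The containing [document()].
#' @return 1-based sentence index.
#' @export
event_sentence <- function(event, doc) span_sentence(event$trigger, doc$sentences)

validate_document <- function(doc) {
  ids <- c(names(doc$entities), names(doc$events))
  if (anyDuplicated(ids))
    stop("duplicate annotation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (e in doc$entities) {
    if (!identical(substr0(doc$text, e$span$start, e$span$end), e$span$text))
      stop("integrity error: entity ", e$id, " surface '", e$span$text,
           "' does not match document text at [", e$span$start, ", ",
           e$span$end, ")")
    span_sentence(e$span, doc$sentences)
  }
  for (ev in doc$events) {
    if (!identical(substr0(doc$text, ev$trigger$start, ev$trigger$end),
                   ev$trigger$text))
      stop("integrity error: trigger of ", ev$id, " surface mismatch")
    span_sentence(ev$trigger, doc$sentences)
    for (p in ev$participants) {
      pool <- if (p$ref_type == "entity") doc$entities else doc$events
      if (is.null(pool[[p$ref]]))
        stop("resolution error: ", ev$id, " references unknown ",
             p$ref_type, " id ", p$ref)
    }
    if (!is.na(ev$location) && is.null(doc$entities[[ev$location]]))
      stop("resolution error: ", ev$id, " references unknown location entity ",
           ev$location)
  }
  check_acyclic(doc)
  invisible(doc)
}

check_acyclic <- function(doc) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      stop("structure error: cyclic event nesting involving ", id)
    if (isTRUE(state[[id]])) return(invisible())
    for (p in doc$events[[id]]$participants)
      if (p$ref_type == "event") visit(p$ref, c(stack, id))
    assign(id, TRUE, envir = state)
  }
  for (id in names(doc$events)) visit(id, character())
  invisible(doc)
}

# ---------------------------------------------------------------------------
# Standoff reading / writing
#
# T-records:  id TAB type SPACE start SPACE end TAB surface
# E-records:  id TAB Type:Ttrig Role:Arg ...
# M-records:  id TAB Negation E#    (other M types preserved, ignored)
# Location arguments use the role names AtLoc / ToLoc / Loc and are stored
# as the event's location attribute rather than as ordinary participants.
# ---------------------------------------------------------------------------

LOCATION_ROLES <- c("AtLoc", "ToLoc", "Loc", "Location")

parse_t_records <- function(lines) {
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("malformed T-record: '", ln, "'")
    head <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(head) != 3L)
      stop("malformed T-record header: '", ln, "'")
    out[[parts[1]]] <- list(id = parts[1], type = head[1],
                            start = as.integer(head[2]),
                            end = as.integer(head[3]), text = parts[3])
  }
  out
}

#' Read a document from BioNLP-ST-style standoff annotation
#'
#' @param text_content Raw document text (one sentence per line unless
#'   `sentences` is given).
#' @param entity_lines The `.a1` content: given entities as T-records.
#' @param event_lines The `.a2` content: trigger T-records, E-records, and
#'   M-records (`M# Negation E#` marks a negated event; other modification
#'   types are preserved but ignored downstream).
#' @param doc_id Document identifier.
#' @param sentences Optional sentence span data frame (see [document()]).
#' @return A [document()].  Dangling references, span/text mismatches and
#'   cyclic event nesting raise errors naming the offending id.
#' @export
read_standoff <- function(text_content, entity_lines, event_lines,
                          doc_id = "doc", sentences = NULL) {
  split_lines <- function(x) {
    if (length(x) == 1L) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
    x[nzchar(x)]
  }
  a1 <- split_lines(entity_lines)
  a2 <- split_lines(event_lines)
  rec_kind <- function(lines, prefix) lines[startsWith(lines, prefix)]

  t_recs <- c(parse_t_records(rec_kind(a1, "T")),
              parse_t_records(rec_kind(a2, "T")))
  e_lines <- rec_kind(a2, "E")
  m_lines <- rec_kind(a2, "M")

  events <- list()
  triggers_used <- character()
  for (ln in e_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    eid <- parts[1]
    args <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    kv <- strsplit(args, ":", fixed = TRUE)
    type_trig <- kv[[1]]
    trig <- t_recs[[type_trig[2]]]
    if (is.null(trig))
      stop("resolution error: event ", eid, " references unknown trigger ",
           type_trig[2])
    triggers_used <- c(triggers_used, type_trig[2])
    participants <- list(); location <- NA_character_
    for (a in kv[-1]) {
      role <- sub("[0-9]+$", "", a[1])           # Theme2 -> Theme
      ref <- a[2]
      if (role %in% LOCATION_ROLES) {
        location <- ref
      } else {
        participants <- c(participants, list(list(
          role = tolower(role), ref = ref,
          ref_type = if (startsWith(ref, "E")) "event" else "entity")))
      }
    }
    events[[eid]] <- list(id = eid, type = trig$type,
                          trigger = text_span(trig$start, trig$end, trig$text),
                          participants = participants, location = location)
  }

  mods <- data.frame(id = character(), type = character(), event_id = character())
  negated <- character()
  for (ln in m_lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) != 3L) stop("malformed M-record: '", ln, "'")
    if (is.null(events[[parts[3]]]))
      stop("resolution error: modification ", parts[1],
           " references unknown event ", parts[3])
    if (parts[2] == "Negation") negated <- c(negated, parts[3])
    else mods <- rbind(mods, data.frame(id = parts[1], type = parts[2],
                                        event_id = parts[3]))
  }

  entity_ids <- setdiff(names(t_recs), triggers_used)
  # T-records in .a1 are entities even if some event also points at them
  entity_ids <- union(names(parse_t_records(rec_kind(a1, "T"))), entity_ids)
  entities <- lapply(t_recs[entity_ids], function(t)
    entity(t$id, t$type, text_span(t$start, t$end, t$text)))

  ev_objs <- lapply(events, function(ev)
    bio_event(ev$id, ev$type, ev$trigger, ev$participants, ev$location,
              if (ev$id %in% negated) "negated" else "positive"))

  document(doc_id, text_content, entities, ev_objs, sentences = sentences,
           modifications = mods)
}

#' Serialize a document to standoff records
#'
#' Annotation ids are regenerated on write (`T1..`, `E1..`, `M1..`); document
#' equality for round-trip purposes is therefore structural, not id-based.
#' Each negated event yields exactly one `M# Negation E#` record.
#'
#' @param doc A valid [document()]; invariant violations refuse to serialize.
#' @return `list(entity_lines =, event_lines =)`, the `.a1` and `.a2` file
#'   contents as single strings.
#' @export
write_standoff <- function(doc) {
  validate_document(doc)
  fmt_t <- function(id, type, span)
    paste0(id, "\t", type, " ", span$start, " ", span$end, "\t", span$text)

  tmap <- character(); tn <- 0L; a1 <- character(); a2_t <- character()
  for (e in doc$entities) {
    tn <- tn + 1L; id <- paste0("T", tn); tmap[e$id] <- id
    a1 <- c(a1, fmt_t(id, e$type, e$span))
  }
  trig_key <- function(ev) paste(ev$type, ev$trigger$start, ev$trigger$end)
  trig_ids <- character()
  for (ev in doc$events) {
    k <- trig_key(ev)
    if (is.na(trig_ids[k])) {
      tn <- tn + 1L; trig_ids[k] <- paste0("T", tn)
      a2_t <- c(a2_t, fmt_t(trig_ids[k], ev$type, ev$trigger))
    }
  }
  emap <- character(); en <- 0L
  for (ev in doc$events) { en <- en + 1L; emap[ev$id] <- paste0("E", en) }
  a2_e <- character()
  for (ev in doc$events) {
    args <- paste0(ev$type, ":", trig_ids[trig_key(ev)])
    role_seen <- character()
    for (p in ev$participants) {
      role <- paste0(toupper(substring(p$role, 1, 1)), substring(p$role, 2))
      n_prev <- sum(role_seen == role); role_seen <- c(role_seen, role)
      tag <- if (n_prev > 0) paste0(role, n_prev + 1L) else role
      ref <- if (p$ref_type == "entity") tmap[p$ref] else emap[p$ref]
      args <- paste(args, paste0(tag, ":", ref))
    }
    if (!is.na(ev$location))
      args <- paste(args, paste0("AtLoc:", tmap[ev$location]))
    a2_e <- c(a2_e, paste0(emap[ev$id], "\t", args))
  }
  mn <- 0L; a2_m <- character()
  for (i in seq_len(nrow(doc$modifications))) {
    mn <- mn + 1L
    a2_m <- c(a2_m, paste0("M", mn, "\t", doc$modifications$type[i], " ",
                           emap[doc$modifications$event_id[i]]))
  }
  for (ev in doc$events) if (ev$polarity == "negated") {
    mn <- mn + 1L
    a2_m <- c(a2_m, paste0("M", mn, "\tNegation ", emap[ev$id]))
  }
  list(entity_lines = paste(a1, collapse = "\n"),
       event_lines = paste(c(a2_t, a2_e, a2_m), collapse = "\n"))
}

#' Canonical (id-free) form of a document
#'
#' Replaces annotation ids with structural keys so that two documents that
#' differ only in id numbering compare equal.  Used by round-trip tests.
#'
#' @param doc A [document()].
#' @return A plain list suitable for `identical()` comparison.
#' @export
doc_canonical <- function(doc) {
  ekey <- function(e) paste(e$type, e$span$start, e$span$end, sep = "|")
  entmap <- vapply(doc$entities, ekey, "")
  evkey <- new.env(parent = emptyenv())
  key_of <- function(id) {
    if (!is.null(evkey[[id]])) return(evkey[[id]])
    ev <- doc$events[[id]]
    parts <- vapply(ev$participants, function(p) {
      ref <- if (p$ref_type == "entity") entmap[[p$ref]] else key_of(p$ref)
      paste(p$role, p$ref_type, ref, sep = "=")
    }, "")
    k <- paste(ev$type, ev$trigger$start, ev$trigger$end, ev$polarity,
               paste(sort(parts), collapse = ";"),
               if (is.na(ev$location)) "" else entmap[[ev$location]],
               sep = "|")
    assign(id, k, envir = evkey)
    k
  }
  list(doc_id = doc$doc_id, text = doc$text,
       sentences = doc$sentences,
       entities = sort(unname(entmap)),
       events = sort(unname(vapply(names(doc$events), key_of, ""))))
}

#' Corpus-level polarity statistics
#'
#' @param docs A list of [document()]s (or a corpus object).
#' @return `list(total_events, negated_events, negation_percentage)`; the
#'   percentage is `100 * negated / total` rounded to one decimal, and `NA`
#'   (undefined, not 0) when the corpus has no events.
#' @export
corpus_stats <- function(docs) {
  if (inherits(docs, "negev_corpus")) docs <- docs$documents
  if (inherits(docs, "negev_document")) docs <- list(docs)
  total <- 0L; negated <- 0L
  for (d in docs) {
    total <- total + length(d$events)
    negated <- negated +
      sum(vapply(d$events, function(e) e$polarity == "negated", logical(1)))
  }
  pct <- if (total == 0L) NA_real_ else round(100 * negated / total, 1)
  list(total_events = total, negated_events = negated,
       negation_percentage = pct)
}

#' @export
print.negev_document <- function(x, ...) {
  st <- corpus_stats(list(x))
  cat("<negev_document> ", x$doc_id, ": ", nrow(x$sentences), " sentences, ",
      length(x$entities), " entities, ", st$total_events, " events (",
      st$negated_events, " negated)\n", sep = "")
  invisible(x)
}
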