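# ---------------------------------------------------------------------------
# Synthetic standoff corpus generator
#
# Each sentence instantiates a template with a known bracketing and
# dependency skeleton, so the emitted fixture parses are exact and the whole
# corpus is reproducible from the seed.  Negations of the five observed
# types are planted at configurable rates:
#   inherent    — the trigger itself is a negative word (unaffected, ...)
#   trigger     — an explicit cue modifies the trigger ("does not activate")
#   participant — the cue modifies a participant phrase ("Y but not Z")
#   attribute   — the cue modifies a location phrase ("in L1 but not in L2")
#   contrast    — paired clauses, negated second conjunct, no explicit cue
# Non-negated sentences include distractors: a deactivated "not only"
# pattern, and a cue scoping over a non-negated event ("in the absence of").
# ---------------------------------------------------------------------------

PROTEINS <- c("IL-2", "IL-4", "IL-12", "IFN-alpha", "TNF-alpha", "STAT1",
              "STAT3", "NF-kappaB", "Rac1", "Cdc42", "IRF-1", "MKK3",
              "MKK4", "MKK6", "GATA3", "FOXP3", "p38", "TRAF6")
CELL_TYPES <- c("monocytes", "neutrophils", "lymphocytes", "T-cells",
                "B-cells", "macrophages", "hepatocytes", "fibroblasts")

# transitive verb families keyed by event type
TRANS_VERBS <- list(
  positive_regulation = c("activate", "induce", "enhance", "upregulate"),
  negative_regulation = c("inhibit", "suppress", "downregulate"),
  regulation = c("regulate", "modulate"),
  binding = c("bind"),
  phosphorylation = c("phosphorylate"))
# locative participle families ("Y is <VBN> in <cells>")
LOC_VERBS <- c(gene_expression = "express", transcription = "transcribe",
               protein_catabolism = "degrade", localization = "localize")
# nominal inner-event triggers ("<Y> expression")
NOMINALS <- c(gene_expression = "expression", transcription = "transcription",
              protein_catabolism = "degradation",
              phosphorylation = "phosphorylation")
INHERENT_CUES <- c("unaffected", "insensitive", "independent")
TRIGGER_CUE_FORMS <- c("not", "cannot", "never", "fail", "could not")

#' Generator configuration
#'
#' Defaults encode the observed study conditions: a corpus-wide negation
#' rate of 6.3% (the three public bio-event corpora range 6.1-6.4%), the
#' micro-averaged distribution of the five negation types
#' (12/63/11/6/8%), a complex-event rate of 25% with complex events 2.5
#' times more likely to be negated than simple ones.
#'
#' @param n_sentences Number of sentences.
#' @param negation_rate Fraction of sentences carrying a planted negated
#'   event.
#' @param type_mix Named probabilities over
#'   `c("inherent","trigger","participant","attribute","contrast")`; must
#'   sum to 1.
#' @param cue_inventory Lexicon (object or name) the trigger-negation
#'   templates draw their cues from.
#' @param complex_event_rate Marginal fraction of complex focus events.
#' @param complex_negation_enrichment Odds multiplier for negation on
#'   complex events.
#' @param distractor_rates Named fractions of *positive* sentences built
#'   from the deactivated-"not only" template and from the
#'   cue-over-positive-event template.
#' @param sentences_per_doc Sentences grouped into each document.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   corpus.
#' @return An object of class `"negev_config"`.
#' @export
generator_config <- function(n_sentences = 1000L,
                             negation_rate = 0.063,
                             type_mix = c(inherent = 0.12, trigger = 0.63,
                                          participant = 0.11,
                                          attribute = 0.06, contrast = 0.08),
                             cue_inventory = "c40",
                             complex_event_rate = 0.25,
                             complex_negation_enrichment = 2.5,
                             distractor_rates = c(not_only = 0.05,
                                                  cue_positive = 0.07),
                             sentences_per_doc = 8L,
                             seed = 1L) {
  if (abs(sum(type_mix) - 1) > 1e-8)
    stop("validation error: type_mix must sum to 1")
  if (negation_rate < 0 || negation_rate > 1 ||
      complex_event_rate < 0 || complex_event_rate > 1)
    stop("validation error: rates must lie in [0, 1]")
  need <- c("inherent", "trigger", "participant", "attribute", "contrast")
  if (!setequal(names(type_mix), need))
    stop("validation error: type_mix needs exactly the five negation types")
  if (is.character(cue_inventory)) cue_inventory <- load_lexicon(cue_inventory)
  structure(list(n_sentences = as.integer(n_sentences),
                 negation_rate = negation_rate, type_mix = type_mix[need],
                 cue_inventory = cue_inventory,
                 complex_event_rate = complex_event_rate,
                 complex_negation_enrichment = complex_negation_enrichment,
                 distractor_rates = distractor_rates,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 seed = as.integer(seed)),
            class = "negev_config")
}

# --- sentence-spec helpers -------------------------------------------------

tkdf <- function(text, lemma, pos)
  data.frame(text = text, lemma = lemma, pos = pos)

edf <- function(...) {
  rows <- list(...)
  data.frame(head = vapply(rows, function(r) as.integer(r[[1]]), 1L),
             dependent = vapply(rows, function(r) as.integer(r[[2]]), 1L),
             label = vapply(rows, function(r) as.character(r[[3]]), ""))
}

nd <- function(label, ...) list(label = label, children = list(...))

finalize_tree <- function(node, tokens) {
  if (is.numeric(node))
    return(list(label = tokens$pos[node], token = as.integer(node),
                surface = tokens$text[node]))
  node$children <- lapply(node$children, finalize_tree, tokens = tokens)
  node
}

vb3 <- function(lemma) {          # third-person singular form
  if (grepl("(s|x|z|ch|sh)$", lemma)) paste0(lemma, "es")
  else paste0(lemma, "s")
}
vbn <- function(lemma) {          # past participle
  if (lemma == "bind") "bound"
  else if (grepl("e$", lemma)) paste0(lemma, "d")
  else paste0(lemma, "ed")
}

ent_ref <- function(i) list(kind = "entity", idx = i)
evt_ref <- function(i) list(kind = "event", idx = i)

sentence_spec <- function(tokens, tree, edges, entities, events, gold) {
  list(tokens = tokens, tree = finalize_tree(tree, tokens), edges = edges,
       entities = entities, events = events, gold = gold)
}

pick <- function(x, n = 1L) if (length(x) == 1L) rep(x, n) else sample(x, n)

sample_trans_type <- function()
  sample(names(TRANS_VERBS), 1L)
sample_loc_type <- function()
  sample(names(LOC_VERBS), 1L)

# --- templates -------------------------------------------------------------
# Each returns a sentence_spec.  Entities are single tokens; events
# reference entities / events by their position in the spec lists.

tpl_plain_simple <- function() {
  type <- sample_trans_type()
  verb <- pick(TRANS_VERBS[[type]])
  nm <- pick(PROTEINS, 2L)
  tokens <- tkdf(c(nm[1], vb3(verb), nm[2], "."),
                 c(nm[1], verb, nm[2], "."),
                 c("NNP", "VBZ", "NNP", "."))
  tree <- nd("S", nd("NP", 1), nd("VP", 2, nd("NP", 3)), 4)
  edges <- edf(c(2, 1, "nsubj"), c(2, 3, "dobj"), c(2, 4, "punct"))
  parts <- if (type == "binding")
    list(list(role = "theme", ref = ent_ref(1)),
         list(role = "theme", ref = ent_ref(2)))
  else
    list(list(role = "cause", ref = ent_ref(1)),
         list(role = "theme", ref = ent_ref(2)))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 3, type = "protein")),
    events = list(list(trigger = 2, type = type, parts = parts,
                       location = NA, polarity = "positive")),
    gold = list(negated = FALSE, neg_type = NA, template = "plain_simple"))
}

tpl_plain_locative <- function() {
  type <- sample_loc_type()
  verb <- LOC_VERBS[[type]]
  nm <- pick(PROTEINS); loc <- pick(CELL_TYPES)
  tokens <- tkdf(c(nm, "is", vbn(verb), "in", loc, "."),
                 c(nm, "be", verb, "in", sub("s$", "", loc), "."),
                 c("NNP", "VBZ", "VBN", "IN", "NNS", "."))
  tree <- nd("S", nd("NP", 1),
             nd("VP", 2, nd("VP", 3, nd("PP", 4, nd("NP", 5)))), 6)
  edges <- edf(c(3, 1, "nsubjpass"), c(3, 2, "aux"), c(3, 4, "prep"),
               c(4, 5, "pobj"), c(3, 6, "punct"))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 5, type = "cell_type")),
    events = list(list(trigger = 3, type = type,
                       parts = list(list(role = "theme", ref = ent_ref(1))),
                       location = 2, polarity = "positive")),
    gold = list(negated = FALSE, neg_type = NA, template = "plain_locative"))
}

tpl_plain_complex <- function() {
  outer_type <- sample(c("positive_regulation", "negative_regulation",
                         "regulation"), 1L)
  verb <- pick(TRANS_VERBS[[outer_type]])
  inner_type <- sample(names(NOMINALS), 1L)
  nom <- NOMINALS[[inner_type]]
  nm <- pick(PROTEINS, 2L)
  tokens <- tkdf(c(nm[1], vb3(verb), nm[2], nom, "."),
                 c(nm[1], verb, nm[2], nom, "."),
                 c("NNP", "VBZ", "NNP", "NN", "."))
  tree <- nd("S", nd("NP", 1), nd("VP", 2, nd("NP", 3, 4)), 5)
  edges <- edf(c(2, 1, "nsubj"), c(2, 4, "dobj"), c(4, 3, "nn"),
               c(2, 5, "punct"))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 3, type = "protein")),
    events = list(
      list(trigger = 4, type = inner_type,
           parts = list(list(role = "theme", ref = ent_ref(2))),
           location = NA, polarity = "positive"),
      list(trigger = 2, type = outer_type,
           parts = list(list(role = "cause", ref = ent_ref(1)),
                        list(role = "theme", ref = evt_ref(1))),
           location = NA, polarity = "positive")),
    gold = list(negated = FALSE, neg_type = NA, template = "plain_complex"))
}

# negated trigger: cue variants over a transitive scaffold; optionally with
# a nested inner event as the object ("does not induce IL-2 expression")
tpl_neg_trigger <- function(cue_form, complex = FALSE) {
  outer_type <- if (complex)
    sample(c("positive_regulation", "negative_regulation", "regulation"), 1L)
  else sample_trans_type()
  verb <- pick(TRANS_VERBS[[outer_type]])
  nm <- pick(PROTEINS, 2L)
  ob <- if (complex) {
    inner_type <- sample(names(NOMINALS), 1L)
    list(texts = c(nm[2], NOMINALS[[inner_type]]),
         lemmas = c(nm[2], NOMINALS[[inner_type]]),
         pos = c("NNP", "NN"),
         np = function(i) nd("NP", i, i + 1L),
         obj_head = function(i) i + 1L,
         extra_edges = function(i) list(c(i + 1L, i, "nn")))
  } else {
    list(texts = nm[2], lemmas = nm[2], pos = "NNP",
         np = function(i) nd("NP", i),
         obj_head = function(i) i,
         extra_edges = function(i) list())
  }

  if (cue_form == "not") {
    pre <- list(texts = c(nm[1], "does", "not", verb),
                lemmas = c(nm[1], "do", "not", verb),
                pos = c("NNP", "VBZ", "RB", "VB"), trig = 4L,
                edges = function(t, o) list(c(t, 1, "nsubj"),
                                            c(t, 2, "aux"), c(t, 3, "neg"),
                                            c(t, o, "dobj")),
                vp = function(t, objnp) nd("VP", 2, 3, nd("VP", t, objnp)))
  } else if (cue_form == "could not") {
    pre <- list(texts = c(nm[1], "could", "not", verb),
                lemmas = c(nm[1], "could", "not", verb),
                pos = c("NNP", "MD", "RB", "VB"), trig = 4L,
                edges = function(t, o) list(c(t, 1, "nsubj"),
                                            c(t, 2, "aux"), c(t, 3, "neg"),
                                            c(t, o, "dobj")),
                vp = function(t, objnp) nd("VP", 2, 3, nd("VP", t, objnp)))
  } else if (cue_form == "cannot") {
    pre <- list(texts = c(nm[1], "cannot", verb),
                lemmas = c(nm[1], "cannot", verb),
                pos = c("NNP", "MD", "VB"), trig = 3L,
                edges = function(t, o) list(c(t, 1, "nsubj"),
                                            c(t, 2, "neg"), c(t, o, "dobj")),
                vp = function(t, objnp) nd("VP", 2, nd("VP", t, objnp)))
  } else if (cue_form == "never") {
    pre <- list(texts = c(nm[1], "never", vb3(verb)),
                lemmas = c(nm[1], "never", verb),
                pos = c("NNP", "RB", "VBZ"), trig = 3L,
                edges = function(t, o) list(c(t, 1, "nsubj"),
                                            c(t, 2, "neg"), c(t, o, "dobj")),
                vp = function(t, objnp) nd("VP", 2, nd("VP", t, objnp)))
  } else {                                  # fail: "X fails to <verb> Y"
    pre <- list(texts = c(nm[1], "fails", "to", verb),
                lemmas = c(nm[1], "fail", "to", verb),
                pos = c("NNP", "VBZ", "TO", "VB"), trig = 4L,
                edges = function(t, o) list(c(2, 1, "nsubj"),
                                            c(2, t, "xcomp"),
                                            c(t, 3, "aux"), c(t, o, "dobj")),
                vp = function(t, objnp)
                  nd("VP", 2, nd("S", nd("VP", 3, nd("VP", t, objnp)))))
  }

  obj_first <- length(pre$texts) + 1L
  dot <- obj_first + length(ob$texts)
  tokens <- tkdf(c(pre$texts, ob$texts, "."),
                 c(pre$lemmas, ob$lemmas, "."),
                 c(pre$pos, ob$pos, "."))
  obj_head <- ob$obj_head(obj_first)
  edges_list <- c(pre$edges(pre$trig, obj_head), ob$extra_edges(obj_first),
                  list(c(pre$trig, dot, "punct")))
  edges <- do.call(edf, edges_list)
  tree <- nd("S", nd("NP", 1), pre$vp(pre$trig, ob$np(obj_first)), dot)

  entities <- list(list(tok = 1, type = "protein"),
                   list(tok = obj_first, type = "protein"))
  if (complex) {
    events <- list(
      list(trigger = obj_first + 1L, type = inner_type,
           parts = list(list(role = "theme", ref = ent_ref(2))),
           location = NA, polarity = "positive"),
      list(trigger = pre$trig, type = outer_type,
           parts = list(list(role = "cause", ref = ent_ref(1)),
                        list(role = "theme", ref = evt_ref(1))),
           location = NA, polarity = "negated"))
  } else {
    parts <- if (outer_type == "binding")
      list(list(role = "theme", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(2)))
    else
      list(list(role = "cause", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(2)))
    events <- list(list(trigger = pre$trig, type = outer_type, parts = parts,
                        location = NA, polarity = "negated"))
  }
  sentence_spec(tokens, tree, edges, entities, events,
    gold = list(negated = TRUE, neg_type = "trigger",
                template = paste0("neg_trigger_",
                                  gsub(" ", "_", cue_form),
                                  if (complex) "_complex" else "")))
}

tpl_inherent <- function(complex = FALSE) {
  cue <- pick(INHERENT_CUES)
  prep <- switch(cue, unaffected = "by", insensitive = "to",
                 independent = "of")
  nm <- pick(PROTEINS, 2L)
  if (complex) {
    inner_type <- sample(names(NOMINALS), 1L)
    nom <- NOMINALS[[inner_type]]
    tokens <- tkdf(c(nm[1], nom, "is", cue, prep, nm[2], "."),
                   c(nm[1], nom, "be", cue, prep, nm[2], "."),
                   c("NNP", "NN", "VBZ", "JJ", "IN", "NNP", "."))
    tree <- nd("S", nd("NP", 1, 2),
               nd("VP", 3, nd("ADJP", 4, nd("PP", 5, nd("NP", 6)))), 7)
    edges <- edf(c(2, 1, "nn"), c(4, 2, "nsubj"), c(4, 3, "cop"),
                 c(4, 5, "prep"), c(5, 6, "pobj"), c(4, 7, "punct"))
    entities <- list(list(tok = 1, type = "protein"),
                     list(tok = 6, type = "protein"))
    events <- list(
      list(trigger = 2, type = inner_type,
           parts = list(list(role = "theme", ref = ent_ref(1))),
           location = NA, polarity = "positive"),
      list(trigger = 4, type = "regulation",
           parts = list(list(role = "theme", ref = evt_ref(1)),
                        list(role = "cause", ref = ent_ref(2))),
           location = NA, polarity = "negated"))
  } else {
    tokens <- tkdf(c(nm[1], "is", cue, prep, nm[2], "."),
                   c(nm[1], "be", cue, prep, nm[2], "."),
                   c("NNP", "VBZ", "JJ", "IN", "NNP", "."))
    tree <- nd("S", nd("NP", 1),
               nd("VP", 2, nd("ADJP", 3, nd("PP", 4, nd("NP", 5)))), 6)
    edges <- edf(c(3, 1, "nsubj"), c(3, 2, "cop"), c(3, 4, "prep"),
                 c(4, 5, "pobj"), c(3, 6, "punct"))
    entities <- list(list(tok = 1, type = "protein"),
                     list(tok = 5, type = "protein"))
    events <- list(
      list(trigger = 3, type = "regulation",
           parts = list(list(role = "theme", ref = ent_ref(1)),
                        list(role = "cause", ref = ent_ref(2))),
           location = NA, polarity = "negated"))
  }
  sentence_spec(tokens, tree, edges, entities, events,
    gold = list(negated = TRUE, neg_type = "inherent",
                template = paste0("inherent", if (complex) "_complex" else "")))
}

tpl_neg_participant <- function() {
  type <- sample_trans_type()
  verb <- pick(TRANS_VERBS[[type]])
  nm <- pick(PROTEINS, 3L)
  tokens <- tkdf(c(nm[1], vb3(verb), nm[2], "but", "not", nm[3], "."),
                 c(nm[1], verb, nm[2], "but", "not", nm[3], "."),
                 c("NNP", "VBZ", "NNP", "CC", "RB", "NNP", "."))
  tree <- nd("S", nd("NP", 1),
             nd("VP", 2, nd("NP", nd("NP", 3), 4, 5, nd("NP", 6))), 7)
  edges <- edf(c(2, 1, "nsubj"), c(2, 3, "dobj"), c(3, 4, "cc"),
               c(3, 6, "conj"), c(6, 5, "neg"), c(2, 7, "punct"))
  mk_parts <- function(theme_ent)
    if (type == "binding")
      list(list(role = "theme", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(theme_ent)))
    else
      list(list(role = "cause", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(theme_ent)))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 3, type = "protein"),
                    list(tok = 6, type = "protein")),
    events = list(
      list(trigger = 2, type = type, parts = mk_parts(2),
           location = NA, polarity = "positive"),
      list(trigger = 2, type = type, parts = mk_parts(3),
           location = NA, polarity = "negated")),
    gold = list(negated = TRUE, neg_type = "participant",
                template = "neg_participant"))
}

tpl_neg_attribute <- function() {
  type <- sample(c("gene_expression", "transcription",
                   "protein_catabolism"), 1L)
  verb <- LOC_VERBS[[type]]
  nm <- pick(PROTEINS); loc <- pick(CELL_TYPES, 2L)
  tokens <- tkdf(
    c(nm, "is", vbn(verb), "in", loc[1], "but", "not", "in", loc[2], "."),
    c(nm, "be", verb, "in", sub("s$", "", loc[1]), "but", "not", "in",
      sub("s$", "", loc[2]), "."),
    c("NNP", "VBZ", "VBN", "IN", "NNS", "CC", "RB", "IN", "NNS", "."))
  tree <- nd("S", nd("NP", 1),
             nd("VP", 2,
                nd("VP", 3,
                   nd("PP", nd("PP", 4, nd("NP", 5)), 6, 7,
                      nd("PP", 8, nd("NP", 9))))), 10)
  edges <- edf(c(3, 1, "nsubjpass"), c(3, 2, "aux"), c(3, 4, "prep"),
               c(4, 5, "pobj"), c(4, 6, "cc"), c(4, 8, "conj"),
               c(8, 7, "neg"), c(8, 9, "pobj"), c(3, 10, "punct"))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 5, type = "cell_type"),
                    list(tok = 9, type = "cell_type")),
    events = list(
      list(trigger = 3, type = type,
           parts = list(list(role = "theme", ref = ent_ref(1))),
           location = 2, polarity = "positive"),
      list(trigger = 3, type = type,
           parts = list(list(role = "theme", ref = ent_ref(1))),
           location = 3, polarity = "negated")),
    gold = list(negated = TRUE, neg_type = "attribute",
                template = "neg_attribute"))
}

tpl_contrast <- function() {
  type <- sample_trans_type()
  verb <- pick(TRANS_VERBS[[type]])
  nm <- pick(PROTEINS, 3L)
  tokens <- tkdf(
    c(nm[1], ",", "in", "contrast", "to", nm[2], ",", vb3(verb), nm[3], "."),
    c(nm[1], ",", "in", "contrast", "to", nm[2], ",", verb, nm[3], "."),
    c("NNP", ",", "IN", "NN", "TO", "NNP", ",", "VBZ", "NNP", "."))
  tree <- nd("S",
             nd("NP", nd("NP", 1), 2,
                nd("PP", 3, nd("NP", 4, nd("PP", 5, nd("NP", 6)))), 7),
             nd("VP", 8, nd("NP", 9)), 10)
  edges <- edf(c(8, 1, "nsubj"), c(8, 9, "dobj"), c(1, 3, "prep"),
               c(3, 4, "pobj"), c(4, 5, "prep"), c(5, 6, "pobj"),
               c(8, 2, "punct"), c(8, 7, "punct"), c(8, 10, "punct"))
  mk_parts <- function(cause_ent)
    if (type == "binding")
      list(list(role = "theme", ref = ent_ref(cause_ent)),
           list(role = "theme", ref = ent_ref(3)))
    else
      list(list(role = "cause", ref = ent_ref(cause_ent)),
           list(role = "theme", ref = ent_ref(3)))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 6, type = "protein"),
                    list(tok = 9, type = "protein")),
    events = list(
      list(trigger = 8, type = type, parts = mk_parts(1),
           location = NA, polarity = "positive"),
      list(trigger = 8, type = type, parts = mk_parts(2),
           location = NA, polarity = "negated")),
    gold = list(negated = TRUE, neg_type = "contrast",
                template = "contrast"))
}

tpl_distractor_not_only <- function() {
  types <- c(sample_trans_type(), sample_trans_type())
  verbs <- c(pick(TRANS_VERBS[[types[1]]]), pick(TRANS_VERBS[[types[2]]]))
  nm <- pick(PROTEINS, 3L)
  tokens <- tkdf(
    c(nm[1], "not", "only", vb3(verbs[1]), nm[2], "but", "also",
      vb3(verbs[2]), nm[3], "."),
    c(nm[1], "not", "only", verbs[1], nm[2], "but", "also", verbs[2],
      nm[3], "."),
    c("NNP", "RB", "RB", "VBZ", "NNP", "CC", "RB", "VBZ", "NNP", "."))
  tree <- nd("S", nd("NP", 1),
             nd("VP", nd("VP", 2, 3, 4, nd("NP", 5)), 6,
                nd("VP", 7, 8, nd("NP", 9))), 10)
  edges <- edf(c(4, 1, "nsubj"), c(4, 2, "neg"), c(2, 3, "mwe"),
               c(4, 5, "dobj"), c(4, 6, "cc"), c(4, 8, "conj"),
               c(8, 7, "advmod"), c(8, 9, "dobj"), c(4, 10, "punct"))
  mk_parts <- function(theme_ent, type)
    if (type == "binding")
      list(list(role = "theme", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(theme_ent)))
    else
      list(list(role = "cause", ref = ent_ref(1)),
           list(role = "theme", ref = ent_ref(theme_ent)))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 5, type = "protein"),
                    list(tok = 9, type = "protein")),
    events = list(
      list(trigger = 4, type = types[1], parts = mk_parts(2, types[1]),
           location = NA, polarity = "positive"),
      list(trigger = 8, type = types[2], parts = mk_parts(3, types[2]),
           location = NA, polarity = "positive")),
    gold = list(negated = FALSE, neg_type = NA,
                template = "distractor_not_only"))
}

tpl_distractor_cue_positive <- function() {
  type <- sample_trans_type()
  verb <- pick(TRANS_VERBS[[type]])
  nm <- pick(PROTEINS, 3L)
  tokens <- tkdf(
    c(nm[1], vb3(verb), nm[2], "in", "the", "absence", "of", nm[3], "."),
    c(nm[1], verb, nm[2], "in", "the", "absence", "of", nm[3], "."),
    c("NNP", "VBZ", "NNP", "IN", "DT", "NN", "IN", "NNP", "."))
  tree <- nd("S", nd("NP", 1),
             nd("VP", 2, nd("NP", 3),
                nd("PP", 4, nd("NP", 5, 6, nd("PP", 7, nd("NP", 8))))), 9)
  edges <- edf(c(2, 1, "nsubj"), c(2, 3, "dobj"), c(2, 4, "prep"),
               c(4, 6, "pobj"), c(6, 5, "det"), c(6, 7, "prep"),
               c(7, 8, "pobj"), c(2, 9, "punct"))
  parts <- if (type == "binding")
    list(list(role = "theme", ref = ent_ref(1)),
         list(role = "theme", ref = ent_ref(2)))
  else
    list(list(role = "cause", ref = ent_ref(1)),
         list(role = "theme", ref = ent_ref(2)))
  sentence_spec(tokens, tree, edges,
    entities = list(list(tok = 1, type = "protein"),
                    list(tok = 3, type = "protein"),
                    list(tok = 8, type = "protein")),
    events = list(list(trigger = 2, type = type, parts = parts,
                       location = NA, polarity = "positive")),
    gold = list(negated = FALSE, neg_type = NA,
                template = "distractor_cue_positive"))
}

# --- corpus assembly -------------------------------------------------------

#' Generate a synthetic standoff corpus with planted negations
#'
#' @param config A [generator_config()].
#' @return An object of class `"negev_corpus"`: `documents` (list of
#'   [document()]s), `parses` (fixture parses keyed by sentence text, token
#'   offsets sentence-relative), `gold` (one row per event: `doc_id`,
#'   `event_id` — globally unique, `polarity`, `neg_type`, `template`,
#'   `complex`), `plants` (one row per sentence recording the planted
#'   template), and the config.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "negev_config"))
  set.seed(config$seed)
  n <- config$n_sentences
  r <- config$negation_rate
  cr <- config$complex_event_rate
  w <- config$complex_negation_enrichment
  # P(neg | simple) scaled so the marginal equals r with enrichment w
  denom <- (1 - cr) + cr * w
  p_complex_neg <- if (r > 0) cr * w / denom else 0
  p_neg_simple <- r / denom
  p_complex_pos <- if (r < 1) cr * (1 - w * p_neg_simple) / (1 - r) else 0

  cue_displays <- vapply(config$cue_inventory$entries, `[[`, "", "display")
  trig_cues <- intersect(cue_displays, TRIGGER_CUE_FORMS)
  if (length(trig_cues) == 0L) trig_cues <- "not"   # every list carries "not"

  dr <- config$distractor_rates
  specs <- vector("list", n)
  plants <- data.frame(sentence = seq_len(n), negated = logical(n),
                       neg_type = rep(NA_character_, n),
                       template = rep(NA_character_, n))
  for (i in seq_len(n)) {
    negated <- stats::runif(1) < r
    if (negated) {
      ntype <- sample(names(config$type_mix), 1L, prob = config$type_mix)
      complex <- stats::runif(1) < p_complex_neg
      sp <- switch(ntype,
        inherent = tpl_inherent(complex),
        trigger = tpl_neg_trigger(pick(trig_cues), complex),
        participant = tpl_neg_participant(),
        attribute = tpl_neg_attribute(),
        contrast = tpl_contrast())
      plants$negated[i] <- TRUE
      plants$neg_type[i] <- ntype
    } else {
      u <- stats::runif(1)
      if (u < dr[["not_only"]]) {
        sp <- tpl_distractor_not_only()
      } else if (u < dr[["not_only"]] + dr[["cue_positive"]]) {
        sp <- tpl_distractor_cue_positive()
      } else if (stats::runif(1) < p_complex_pos) {
        sp <- tpl_plain_complex()
      } else if (stats::runif(1) < 0.35) {
        sp <- tpl_plain_locative()
      } else {
        sp <- tpl_plain_simple()
      }
    }
    plants$template[i] <- sp$gold$template
    specs[[i]] <- sp
  }

  docs <- list(); parses <- list()
  gold_rows <- list()
  ev_counter <- 0L; t_counter <- 0L
  spd <- config$sentences_per_doc
  doc_ids <- split(seq_len(n), ceiling(seq_len(n) / spd))
  for (d in seq_along(doc_ids)) {
    idx <- doc_ids[[d]]
    doc_id <- sprintf("doc%04d", d)
    offs <- 0L; texts <- character()
    entities <- list(); events <- list()
    for (si in seq_along(idx)) {
      sp <- specs[[idx[si]]]
      words <- sp$tokens$text
      starts <- offs + c(0L, cumsum(nchar(words) + 1L)[-length(words)])
      ends <- starts + nchar(words)
      stext <- paste(words, collapse = " ")
      texts <- c(texts, stext)

      if (is.null(parses[[stext]])) {
        tok <- sp$tokens
        tok$start <- starts - offs; tok$end <- ends - offs
        parses[[stext]] <- parse_result(tok, sp$edges, sp$tree)
      }

      ent_ids <- character(length(sp$entities))
      for (j in seq_along(sp$entities)) {
        t_counter <- t_counter + 1L
        ent_ids[j] <- paste0("T", t_counter)
        tk <- sp$entities[[j]]$tok
        entities[[ent_ids[j]]] <- entity(
          ent_ids[j], sp$entities[[j]]$type,
          text_span(starts[tk], ends[tk], words[tk]))
      }
      evt_ids <- character(length(sp$events))
      for (j in seq_along(sp$events)) {
        ev_counter <- ev_counter + 1L
        evt_ids[j] <- paste0("E", ev_counter)
      }
      for (j in seq_along(sp$events)) {
        ev <- sp$events[[j]]
        parts <- lapply(ev$parts, function(p)
          if (p$ref$kind == "entity")
            list(role = p$role, ref = ent_ids[p$ref$idx],
                 ref_type = "entity")
          else
            list(role = p$role, ref = evt_ids[p$ref$idx],
                 ref_type = "event"))
        tk <- ev$trigger
        events[[evt_ids[j]]] <- bio_event(
          evt_ids[j], ev$type,
          text_span(starts[tk], ends[tk], words[tk]), parts,
          location = if (is.na(ev$location)) NA_character_
                     else ent_ids[ev$location],
          polarity = ev$polarity)
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          doc_id = doc_id, event_id = evt_ids[j], polarity = ev$polarity,
          neg_type = if (ev$polarity == "negated")
            plants$neg_type[idx[si]] else NA_character_,
          template = sp$gold$template,
          complex = any(vapply(ev$parts, function(p)
            p$ref$kind == "event", logical(1))))
      }
      offs <- offs + nchar(stext) + 1L
    }
    docs[[doc_id]] <- document(doc_id, paste(texts, collapse = "\n"),
                               entities, events)
  }

  gold <- if (length(gold_rows)) do.call(rbind, gold_rows)
          else data.frame(doc_id = character(), event_id = character(),
                          polarity = character(), neg_type = character(),
                          template = character(), complex = logical())
  structure(list(documents = docs, parses = parses, gold = gold,
                 plants = plants, config = config),
            class = "negev_corpus")
}

#' @export
print.negev_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat("<negev_corpus> ", length(x$documents), " documents, ",
      nrow(x$plants), " sentences, ", st$total_events, " events (",
      st$negated_events, " negated, ",
      ifelse(is.na(st$negation_percentage), "-", st$negation_percentage),
      "%)\n", sep = "")
  invisible(x)
}

#' Write a corpus to a directory of standoff triples
#'
#' Emits `<doc>.txt` / `.a1` / `.a2` per document plus `parses.json`
#' (fixture parses keyed by sentence text), `gold.tsv` and `plants.tsv`.
#'
#' @param corpus A `"negev_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    so <- write_standoff(doc)
    base <- file.path(dir, doc$doc_id)
    writeLines(doc$text, paste0(base, ".txt"))
    writeLines(so$entity_lines, paste0(base, ".a1"))
    writeLines(so$event_lines, paste0(base, ".a2"))
  }
  pj <- lapply(corpus$parses, function(p)
    list(tokens = p$tokens, edges = p$edges,
         tree = write_bracket_tree(p$tree)))
  jsonlite::write_json(pj, file.path(dir, "parses.json"), dataframe = "columns")
  utils::write.table(corpus$gold, file.path(dir, "gold.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(corpus$plants, file.path(dir, "plants.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing the standoff triples and fixtures.
#' @return A `"negev_corpus"` (without the generating config).
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list()
  for (tx in txts) {
    base <- sub("\\.txt$", "", tx)
    doc_id <- basename(base)
    docs[[doc_id]] <- read_standoff(
      paste(readLines(tx), collapse = "\n"),
      paste(readLines(paste0(base, ".a1")), collapse = "\n"),
      paste(readLines(paste0(base, ".a2")), collapse = "\n"),
      doc_id = doc_id)
  }
  parses <- NULL
  pj_path <- file.path(dir, "parses.json")
  if (file.exists(pj_path)) {
    pj <- jsonlite::read_json(pj_path, simplifyVector = TRUE)
    parses <- lapply(pj, function(p)
      parse_result(as.data.frame(p$tokens), as.data.frame(p$edges), p$tree))
  }
  gold <- NULL
  if (file.exists(file.path(dir, "gold.tsv")))
    gold <- utils::read.table(file.path(dir, "gold.tsv"), sep = "\t",
                              header = TRUE)
  plants <- NULL
  if (file.exists(file.path(dir, "plants.tsv")))
    plants <- utils::read.table(file.path(dir, "plants.tsv"), sep = "\t",
                                header = TRUE)
  structure(list(documents = docs, parses = parses, gold = gold,
                 plants = plants, config = NULL),
            class = "negev_corpus")
}
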