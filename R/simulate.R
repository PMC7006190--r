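# Seeded generator of schema-conforming standoff corpora. Trigger words
# come from disjoint per-event-type lexicons mixed with noise words, so
# trigger recognition is learnable but not trivial; clause order is fixed
# (non-first-role fillers before the trigger, first-role fillers after),
# giving the relation classifier a positional signal; negation and
# speculation get lexical cues ("not", "may").

#' Configuration for the synthetic corpus generator
#'
#' @param entities_per_sentence integer range (length 2) of extra entity
#'   mentions sampled per sentence beyond those used by events.
#' @param event_density expected number of top-level events per sentence
#'   (Poisson mean, capped at 2).
#' @param nesting_prob probability that an admissible role is filled by a
#'   sub-event rather than an entity.
#' @param modification_prob probability an event carries a
#'   Negation/Speculation modification (split evenly).
#' @param sentences_per_doc integer range of sentences per document.
#' @param noise_words number of noise-word slots sprinkled per sentence
#'   (upper bound; actual count is uniform on 0..noise_words).
#' @param seed integer seed; fixes the corpus byte-for-byte.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(entities_per_sentence = c(0L, 2L),
                             event_density = 1.2,
                             nesting_prob = 0.25,
                             modification_prob = 0.1,
                             sentences_per_doc = c(1L, 2L),
                             noise_words = 3L,
                             seed = 1L) {
  stopifnot(nesting_prob >= 0, nesting_prob <= 1,
            modification_prob >= 0, modification_prob <= 1)
  structure(list(entities_per_sentence = as.integer(entities_per_sentence),
                 event_density = event_density,
                 nesting_prob = nesting_prob,
                 modification_prob = modification_prob,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 noise_words = as.integer(noise_words),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# word lists; curated for the toy schema's type names, synthesised
# otherwise (always disjoint across types)
build_lexicons <- function(schema) {
  curated_ent <- list(
    Gene = c("grk1", "tlr4", "mapk3", "p53", "stat3", "il2"),
    Disease = c("carcinoma", "fibrosis", "sepsis", "lymphoma"))
  curated_trig <- list(
    Expression = c("expression", "transcription", "synthesis",
                   "production", "overexpression"),
    Regulation = c("activates", "inhibits", "promotes", "suppresses",
                   "regulates"))
  ent <- lapply(seq_along(schema$entity_types), function(i) {
    tt <- schema$entity_types[i]
    curated_ent[[tt]] %||% paste0(tolower(tt), "x", 1:5)
  })
  names(ent) <- schema$entity_types
  trig <- lapply(seq_along(schema_event_types(schema)), function(i) {
    tt <- schema_event_types(schema)[i]
    curated_trig[[tt]] %||% paste0(tolower(tt), "w", 1:5)
  })
  names(trig) <- schema_event_types(schema)
  list(entities = ent, triggers = trig,
       starters = c("We", "The", "Notably", "Here"),
       noise = c("observed", "that", "in", "cells", "of", "was",
                 "levels", "during", "tissue", "marked", "analysis",
                 "showed"),
       neg_cue = "not", spec_cue = "may")
}

# mutable sentence builder: tokens is a list of (word, ent, trig)
new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$tokens <- list(); b$entities <- list(); b$triggers <- list()
  b$events <- list()
  b
}

push_token <- function(b, word, ent = NA_integer_, trig = NA_integer_) {
  b$tokens[[length(b$tokens) + 1L]] <-
    list(word = word, ent = ent, trig = trig)
}

push_entity <- function(b, type, word) {
  id <- length(b$entities) + 1L
  b$entities[[id]] <- list(type = type, word = word)
  push_token(b, word, ent = id)
  id
}

# returns the event's local id; appends its clause to the token stream
emit_event <- function(b, schema, cfg, lex, type, depth) {
  decl <- schema$event_types[[type]]
  role_names <- names(decl)
  trig_word <- sample(lex$triggers[[type]], 1)
  mod <- "None"
  if (stats::runif(1) < cfg$modification_prob) {
    mod <- sample(c("Negation", "Speculation"), 1)
    push_token(b, if (mod == "Negation") lex$neg_cue else lex$spec_cue)
  }
  args <- list()
  fill_role <- function(role) {
    r <- decl[[role]]
    k <- r$min + (r$max > r$min && stats::runif(1) < 0.5)
    replicate(k, {
      ent_opts <- intersect(r$fillers, schema$entity_types)
      ev_opts <- intersect(r$fillers, schema_event_types(schema))
      use_event <- length(ev_opts) > 0 &&
        (length(ent_opts) == 0 ||
           (depth < 2 && stats::runif(1) < cfg$nesting_prob))
      if (use_event) {
        if (depth >= 2 && length(ent_opts) == 0)
          stop("unsatisfiable schema: mandatory event-only role at depth cap")
        sub <- emit_event(b, schema, cfg, lex, sample(ev_opts, 1), depth + 1L)
        list(role = role, kind = "event", id = sub)
      } else {
        if (length(ent_opts) == 0)
          stop("unsatisfiable schema: role ", role,
               " has no generatable filler")
        et <- sample(ent_opts, 1)
        eid <- push_entity(b, et, sample(lex$entities[[et]], 1))
        list(role = role, kind = "entity", id = eid)
      }
    }, simplify = FALSE)
  }
  # non-first roles precede the trigger (e.g. Cause trigger Theme)
  for (role in rev(role_names[-1])) args <- c(args, fill_role(role))
  tid <- length(b$triggers) + 1L
  b$triggers[[tid]] <- list(type = type, word = trig_word)
  push_token(b, trig_word, trig = tid)
  if (stats::runif(1) < 0.4) push_token(b, "of")
  for (role in role_names[1]) args <- c(args, fill_role(role))
  evid <- length(b$events) + 1L
  b$events[[evid]] <- list(trigger = tid, args = args, modification = mod)
  evid
}

build_sentence <- function(schema, cfg, lex) {
  b <- new_builder()
  push_token(b, sample(lex$starters, 1))
  noise_budget <- sample(0:cfg$noise_words, 1)
  drop_noise <- function() {
    k <- if (noise_budget > 0) sample(0:min(2, noise_budget), 1) else 0
    noise_budget <<- noise_budget - k
    for (w in sample(lex$noise, k, replace = TRUE)) push_token(b, w)
  }
  drop_noise()
  n_events <- min(stats::rpois(1, cfg$event_density), 2L)
  satisfiable <- Filter(function(tt) {
    decl <- schema$event_types[[tt]]
    all(vapply(decl, function(r)
      r$min == 0 || length(intersect(r$fillers, schema$entity_types)) > 0 ||
        length(intersect(r$fillers, schema_event_types(schema))) > 0, TRUE))
  }, schema_event_types(schema))
  for (k in seq_len(n_events)) {
    emit_event(b, schema, cfg, lex, sample(satisfiable, 1), 1L)
    drop_noise()
  }
  n_extra <- sample(cfg$entities_per_sentence[1]:cfg$entities_per_sentence[2], 1)
  for (k in seq_len(n_extra)) {
    push_token(b, sample(lex$noise, 1))
    et <- sample(schema$entity_types, 1)
    push_entity(b, et, sample(lex$entities[[et]], 1))
  }
  drop_noise()
  push_token(b, ".")
  b
}

#' Generate a seeded synthetic standoff corpus
#'
#' Produces schema-valid, acyclic, single-sentence-scoped documents whose
#' trigger words correlate with event types. The same seed yields a
#' byte-identical corpus.
#'
#' @param n_docs number of documents.
#' @param schema an `event_schema` (default [toy_schema()]).
#' @param cfg a [synthetic_config()].
#' @param prefix document id prefix.
#' @return list of `so_document` with gold events.
#' @export
generate_corpus <- function(n_docs, schema = toy_schema(),
                            cfg = synthetic_config(), prefix = "synth") {
  # fail fast on schemas with no generatable filler anywhere
  for (tt in schema_event_types(schema)) {
    decl <- schema$event_types[[tt]]
    for (rn in names(decl)) {
      r <- decl[[rn]]
      if (r$min > 0 && length(r$fillers) == 0)
        stop("unsatisfiable schema: mandatory role with no fillers")
    }
  }
  lex <- build_lexicons(schema)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    nsent <- sample(cfg$sentences_per_doc[1]:cfg$sentences_per_doc[2], 1)
    builders <- replicate(nsent, build_sentence(schema, cfg, lex),
                          simplify = FALSE)
    # assemble text and character offsets
    text <- ""
    ent_rows <- list(); trig_rows <- list(); events <- list()
    ent_counter <- 0L
    all_ent <- list(); all_trig <- list()
    for (b in builders) {
      ent_off <- length(all_ent); trig_off <- length(all_trig)
      for (tk in b$tokens) {
        if (nchar(text) > 0)
          text <- paste0(text, if (tk$word == ".") "" else " ")
        start <- nchar(text)
        text <- paste0(text, tk$word)
        if (!is.na(tk$ent)) {
          all_ent[[ent_off + tk$ent]] <-
            list(type = b$entities[[tk$ent]]$type, start = start,
                 end = start + nchar(tk$word), text = tk$word)
        }
        if (!is.na(tk$trig)) {
          all_trig[[trig_off + tk$trig]] <-
            list(type = b$triggers[[tk$trig]]$type, start = start,
                 end = start + nchar(tk$word), text = tk$word)
        }
      }
      text <- paste0(text, " ")
      ev_off <- length(events)
      for (ei in seq_along(b$events)) {
        ev <- b$events[[ei]]
        events[[ev_off + ei]] <- list(trigger = trig_off + ev$trigger,
                                      args = lapply(ev$args, function(a) {
                                        a$id <- a$id +
                                          if (a$kind == "event") ev_off else ent_off
                                        a
                                      }),
                                      modification = ev$modification)
      }
    }
    text <- sub(" +$", "", text)
    ne <- length(all_ent)
    ent_df <- if (ne > 0) data.frame(
      id = sprintf("T%d", seq_len(ne)),
      type = vapply(all_ent, `[[`, "", "type"),
      start = vapply(all_ent, `[[`, 0, "start"),
      end = vapply(all_ent, `[[`, 0, "end"),
      text = vapply(all_ent, `[[`, "", "text")) else NULL
    nt <- length(all_trig)
    trig_df <- if (nt > 0) data.frame(
      id = sprintf("T%d", ne + seq_len(nt)),
      type = vapply(all_trig, `[[`, "", "type"),
      start = vapply(all_trig, `[[`, 0, "start"),
      end = vapply(all_trig, `[[`, 0, "end"),
      text = vapply(all_trig, `[[`, "", "text")) else NULL
    ev_list <- list()
    for (ei in seq_along(events)) {
      ev <- events[[ei]]
      eid <- sprintf("E%d", ei)
      roles <- vapply(ev$args, `[[`, "", "role")
      kinds <- vapply(ev$args, `[[`, "", "kind")
      fids <- vapply(seq_along(ev$args), function(k)
        if (kinds[k] == "event") sprintf("E%d", ev$args[[k]]$id)
        else sprintf("T%d", ev$args[[k]]$id), "")
      ev_list[[eid]] <- new_event(eid, sprintf("T%d", ne + ev$trigger),
                                  roles, fids,
                                  ifelse(kinds == "event", "event", "entity"),
                                  ev$modification)
    }
    docs[[d]] <- so_document(sprintf("%s%03d", prefix, d), text,
                             entities = ent_df, triggers = trig_df,
                             events = ev_list)
  }
  docs
}

#' Corpus statistics
#'
#' @param docs list of `so_document`.
#' @return list with `summary` (documents, sentences, words, entities,
#'   triggers, events, modifications) and per-type event/entity counts.
#' @export
corpus_statistics <- function(docs) {
  ev_types <- unlist(lapply(docs, function(d)
    vapply(d$events, function(ev)
      d$triggers$type[match(ev$trigger_id, d$triggers$id)], "")))
  ent_types <- unlist(lapply(docs, function(d) d$entities$type))
  mods <- unlist(lapply(docs, function(d)
    vapply(d$events, `[[`, "", "modification")))
  list(
    summary = data.frame(
      documents = length(docs),
      sentences = sum(vapply(docs, function(d) nrow(d$sentences), 0)),
      words = sum(vapply(docs, function(d) nrow(d$tokens), 0)),
      entities = sum(vapply(docs, function(d) nrow(d$entities), 0)),
      triggers = sum(vapply(docs, function(d) nrow(d$triggers), 0)),
      events = sum(vapply(docs, function(d) length(d$events), 0)),
      modifications = sum(mods != "None")),
    by_event_type = if (length(ev_types))
      as.data.frame(table(type = ev_types)) else NULL,
    by_entity_type = if (length(ent_types))
      as.data.frame(table(type = ent_types)) else NULL)
}
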