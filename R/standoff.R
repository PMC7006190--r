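# BioNLP-ST standoff corpus model and I/O.
#
# Character offsets are 0-based half-open throughout (brat convention):
# text slice of [start, end) is substr(text, start + 1, end).

slice_text <- function(text, start, end) substring(text, start + 1L, end)

#' Split text into sentence character spans
#'
#' Rule-based splitter: a sentence boundary is a run of terminal
#' punctuation (`.`, `?`, `!`) followed by whitespace and a capital letter
#' or digit, unless the word preceding the period is a known abbreviation
#' (e.g. "e.g.", "et al.", "Fig."). The returned spans partition the whole
#' text; inter-sentence whitespace is attached to the following sentence.
#'
#' @param text document text (single string).
#' @return data.frame with 0-based half-open columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar(text)
  if (n == 0) stop("cannot split empty text")
  abbrev <- c("e.g", "i.e", "al", "et al", "Fig", "Figs", "cf", "vs",
              "etc", "Dr", "No", "ca", "approx")
  m <- gregexpr("[.?!]+(?=[ \t\r\n]+[A-Z0-9(])", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1] != -1) {
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      pos <- m[j]          # 1-based position of punctuation start
      # word immediately before the punctuation
      pre <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, max(1, pos - 12), pos - 1))
      if (pre %in% abbrev || sub("\\.$", "", pre) %in% abbrev) next
      bounds <- c(bounds, pos + lens[j] - 1L)  # 0-based end-exclusive == pos+len-1
    }
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

.punct_chars <- c("(", ")", "[", "]", "{", "}", ",", ".", ";", ":", "!",
                  "?", "\"", "'", "<", ">", "%", "&", "*", "+", "=", "~",
                  "^", "#", "$", "@", "`")

#' Tokenize a sentence
#'
#' Whitespace splitting followed by detaching leading/trailing punctuation
#' into their own tokens. Internal hyphens and slashes are preserved so
#' biomedical names like "over-expression" or "IL-2/IL-4" stay single
#' tokens. No external NLP toolkit is involved; offsets are exact.
#'
#' @param sentence_text the sentence string.
#' @param offset character offset of the sentence start within the
#'   document (added to all token offsets).
#' @param sentence_index 1-based sentence index recorded on each token.
#' @return data.frame with columns `text`, `start`, `end` (0-based
#'   half-open, document-relative), `sentence`.
#' @export
tokenize <- function(sentence_text, offset = 0L, sentence_index = 1L) {
  out_text <- character(0); out_start <- integer(0); out_end <- integer(0)
  if (nchar(sentence_text) > 0) {
    m <- gregexpr("\\S+", sentence_text)[[1]]
    if (m[1] != -1) {
      lens <- attr(m, "match.length")
      for (j in seq_along(m)) {
        s <- m[j] - 1L               # 0-based start within sentence
        chunk <- substr(sentence_text, m[j], m[j] + lens[j] - 1L)
        # peel leading punctuation
        lead <- character(0)
        while (nchar(chunk) > 1 && substr(chunk, 1, 1) %in% .punct_chars) {
          lead <- c(lead, substr(chunk, 1, 1))
          chunk <- substr(chunk, 2, nchar(chunk))
        }
        trail <- character(0)
        while (nchar(chunk) > 1 &&
               substr(chunk, nchar(chunk), nchar(chunk)) %in% .punct_chars) {
          trail <- c(substr(chunk, nchar(chunk), nchar(chunk)), trail)
          chunk <- substr(chunk, 1, nchar(chunk) - 1L)
        }
        pieces <- c(lead, chunk, trail)
        pos <- s
        for (p in pieces) {
          out_text <- c(out_text, p)
          out_start <- c(out_start, pos)
          out_end <- c(out_end, pos + nchar(p))
          pos <- pos + nchar(p)
        }
      }
    }
  }
  data.frame(text = out_text,
             start = out_start + offset,
             end = out_end + offset,
             sentence = rep(as.integer(sentence_index), length(out_text)))
}

tokenize_document <- function(text) {
  sents <- split_sentences(text)
  toks <- lapply(seq_len(nrow(sents)), function(i) {
    tokenize(slice_text(text, sents$start[i], sents$end[i]),
             offset = sents$start[i], sentence_index = i)
  })
  list(sentences = sents, tokens = do.call(rbind, toks))
}

# map a char span to the covering contiguous token index range (1-based
# rows of tokens df); NULL if it crosses sentences or covers no token
span_to_tokens <- function(tokens, start, end) {
  idx <- which(tokens$end > start & tokens$start < end)
  if (length(idx) == 0) return(NULL)
  if (length(unique(tokens$sentence[idx])) != 1) return(NULL)
  list(tok_start = min(idx), tok_end = max(idx),
       sentence = tokens$sentence[idx[1]])
}

empty_entities <- function()
  data.frame(id = character(0), type = character(0), start = integer(0),
             end = integer(0), text = character(0), tok_start = integer(0),
             tok_end = integer(0), sentence = integer(0))

empty_triggers <- function() empty_entities()

new_event <- function(id, trigger_id, roles = character(0),
                      filler_ids = character(0),
                      filler_kinds = character(0), modification = "None") {
  list(id = id, trigger_id = trigger_id,
       args = data.frame(role = roles, filler_id = filler_ids,
                         filler_kind = filler_kinds),
       modification = modification)
}

#' Construct a standoff document
#'
#' Splits and tokenizes `text`, attaches entity/trigger mentions and
#' events, verifies all character offsets against the text, and maps
#' mention spans to token spans. Mentions crossing sentence boundaries are
#' an error here (the reader drops them with a warning before calling
#' this).
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param entities,triggers data.frames with `id`, `type`, `start`, `end`
#'   (0-based half-open) and optionally `text`.
#' @param events named list of event records (id, trigger_id, args
#'   data.frame with role/filler_id/filler_kind, modification).
#' @return An object of class `so_document`.
#' @export
so_document <- function(doc_id, text, entities = NULL, triggers = NULL,
                        events = list()) {
  tk <- tokenize_document(text)
  fix_mentions <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(empty_entities())
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    got <- slice_text(text, df$start, df$end)
    if (is.null(df$text)) df$text <- got
    bad <- which(df$text != got)
    if (length(bad) > 0)
      stop(sprintf("integrity error: %s %s quoted text '%s' does not match slice '%s'",
                   what, df$id[bad[1]], df$text[bad[1]], got[bad[1]]), call. = FALSE)
    ts <- te <- si <- integer(nrow(df))
    for (i in seq_len(nrow(df))) {
      mp <- span_to_tokens(tk$tokens, df$start[i], df$end[i])
      if (is.null(mp))
        stop(sprintf("integrity error: %s %s span crosses sentences or covers no token",
                     what, df$id[i]), call. = FALSE)
      ts[i] <- mp$tok_start; te[i] <- mp$tok_end; si[i] <- mp$sentence
    }
    df$tok_start <- ts; df$tok_end <- te; df$sentence <- si
    df[, c("id", "type", "start", "end", "text", "tok_start", "tok_end",
           "sentence")]
  }
  entities <- fix_mentions(entities, "entity")
  triggers <- fix_mentions(triggers, "trigger")
  if (length(events) > 0 && is.null(names(events)))
    names(events) <- vapply(events, `[[`, "", "id")
  doc <- structure(
    list(doc_id = doc_id, text = text, sentences = tk$sentences,
         tokens = tk$tokens, entities = entities, triggers = triggers,
         events = events),
    class = "so_document")
  check_event_refs(doc)
  doc
}

check_event_refs <- function(doc) {
  for (ev in doc$events) {
    if (!ev$trigger_id %in% doc$triggers$id)
      stop(sprintf("reference error: event %s trigger %s not found",
                   ev$id, ev$trigger_id), call. = FALSE)
    for (k in seq_len(nrow(ev$args))) {
      fid <- ev$args$filler_id[k]
      ok <- if (ev$args$filler_kind[k] == "entity")
        fid %in% doc$entities$id else fid %in% names(doc$events)
      if (!ok)
        stop(sprintf("reference error: event %s filler %s not found",
                     ev$id, fid), call. = FALSE)
    }
  }
  cyc <- event_graph_cycle(doc$events)
  if (length(cyc) > 0)
    stop(sprintf("integrity error: event graph cycle at %s", cyc[1]),
         call. = FALSE)
  invisible(doc)
}

#' @export
print.so_document <- function(x, ...) {
  cat(sprintf("<so_document %s: %d sentences, %d tokens, %d entities, %d triggers, %d events>\n",
              x$doc_id, nrow(x$sentences), nrow(x$tokens),
              nrow(x$entities), nrow(x$triggers), length(x$events)))
  invisible(x)
}

parse_mention_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop(sprintf("parse error: %s line %d: expected tab-separated fields",
                 file, lineno), call. = FALSE)
  hdr <- strsplit(parts[2], " +")[[1]]
  if (length(hdr) != 3 || is.na(suppressWarnings(as.integer(hdr[2]))))
    stop(sprintf("parse error: %s line %d: bad mention header '%s'",
                 file, lineno, parts[2]), call. = FALSE)
  list(id = parts[1], type = hdr[1], start = as.integer(hdr[2]),
       end = as.integer(hdr[3]),
       text = if (length(parts) >= 3) parts[3] else NULL)
}

#' Read one document from BioNLP-ST standoff annotation
#'
#' Parses `.a1` entity lines (`Tid<TAB>Type start end<TAB>text`), and
#' optionally `.a2` lines adding trigger mentions (T lines), events
#' (`Eid<TAB>Type:Ttrig Role:Filler ...`) and modifications
#' (`Mid<TAB>Negation|Speculation Eid`). All offsets are verified against
#' the text. Annotations that cross a sentence boundary are dropped with a
#' warning, along with events that depend on them (single-sentence scope).
#'
#' @param txt_text document text.
#' @param a1_text contents of the .a1 file (entities).
#' @param a2_text contents of the .a2 file, or NULL for entities only.
#' @param doc_id document identifier.
#' @return An `so_document`.
#' @export
read_standoff_document <- function(txt_text, a1_text, a2_text = NULL,
                                   doc_id = "doc") {
  tk <- tokenize_document(txt_text)
  read_lines <- function(txt) {
    if (is.null(txt)) return(character(0))
    ln <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    ln[nzchar(trimws(ln))]
  }
  mention_df <- function(lines, file) {
    rows <- lapply(seq_along(lines), function(i) {
      if (!grepl("^T", lines[i])) return(NULL)
      parse_mention_line(lines[i], i, file)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0) return(NULL)
    data.frame(id = vapply(rows, `[[`, "", "id"),
               type = vapply(rows, `[[`, "", "type"),
               start = vapply(rows, `[[`, 0L, "start"),
               end = vapply(rows, `[[`, 0L, "end"),
               text = vapply(rows, function(r) r$text %||% NA_character_, ""))
  }
  verify_and_drop <- function(df, what) {
    if (is.null(df)) return(NULL)
    got <- slice_text(txt_text, df$start, df$end)
    bad <- which(!is.na(df$text) & df$text != got)
    if (length(bad) > 0)
      stop(sprintf("integrity error: %s %s quoted text '%s' != text slice '%s'",
                   what, df$id[bad[1]], df$text[bad[1]], got[bad[1]]),
           call. = FALSE)
    df$text <- got
    cross <- vapply(seq_len(nrow(df)), function(i)
      is.null(span_to_tokens(tk$tokens, df$start[i], df$end[i])), TRUE)
    if (any(cross)) {
      warning(sprintf("dropping %d cross-sentence/unalignable %s mention(s): %s",
                      sum(cross), what, paste(df$id[cross], collapse = ",")))
      df <- df[!cross, , drop = FALSE]
    }
    df
  }
  entities <- verify_and_drop(mention_df(read_lines(a1_text), "a1"), "entity")
  a2_lines <- read_lines(a2_text)
  triggers <- verify_and_drop(mention_df(a2_lines, "a2"), "trigger")

  events <- list()
  mods <- list()
  for (i in seq_along(a2_lines)) {
    ln <- a2_lines[i]
    if (grepl("^E", ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2)
        stop(sprintf("parse error: a2 line %d: bad event line", i), call. = FALSE)
      fields <- strsplit(trimws(parts[2]), " +")[[1]]
      kv <- strsplit(fields, ":", fixed = TRUE)
      if (any(lengths(kv) != 2))
        stop(sprintf("parse error: a2 line %d: bad Role:Filler field", i),
             call. = FALSE)
      roles <- vapply(kv, `[[`, "", 1)
      fillers <- vapply(kv, `[[`, "", 2)
      # strip duplicate-role suffixes (Theme2, Site3 ...)
      roles_plain <- sub("[0-9]+$", "", roles)
      events[[parts[1]]] <- list(
        id = parts[1], type = roles_plain[1], trigger_id = fillers[1],
        roles = roles_plain[-1], fillers = fillers[-1])
    } else if (grepl("^M", ln)) {
      parts <- strsplit(ln, "[\t ]+")[[1]]
      if (length(parts) != 3 || !parts[2] %in% c("Negation", "Speculation"))
        stop(sprintf("parse error: a2 line %d: bad modification line", i),
             call. = FALSE)
      mods[[parts[3]]] <- parts[2]
    } else if (!grepl("^[TE#*M]", ln)) {
      stop(sprintf("parse error: a2 line %d: unrecognised line '%s'",
                   i, substr(ln, 1, 40)), call. = FALSE)
    }
  }
  # resolve events; drop those referencing dropped triggers, recursively
  entity_ids <- if (is.null(entities)) character(0) else entities$id
  trigger_ids <- if (is.null(triggers)) character(0) else triggers$id
  alive <- rep(TRUE, length(events)); names(alive) <- names(events)
  repeat {
    changed <- FALSE
    for (eid in names(events)) {
      if (!alive[[eid]]) next
      ev <- events[[eid]]
      ok <- ev$trigger_id %in% trigger_ids &&
        all(vapply(ev$fillers, function(f) {
          if (grepl("^E", f)) isTRUE(alive[f]) else f %in% entity_ids
        }, TRUE))
      if (!ok) { alive[[eid]] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  dangling <- names(events)[!alive]
  for (eid in names(events)) {
    ev <- events[[eid]]
    if (alive[[eid]]) next
    # distinguish truly dangling references (error) from drops caused by
    # cross-sentence trigger removal (warning)
    refs <- c(ev$trigger_id, ev$fillers)
    unknown <- refs[!grepl("^E", refs) & !refs %in% c(entity_ids, trigger_ids)]
    unknown_e <- refs[grepl("^E", refs) & !refs %in% names(events)]
    if (length(unknown_e) > 0)
      stop(sprintf("reference error: event %s references unknown %s",
                   eid, unknown_e[1]), call. = FALSE)
    if (length(unknown) > 0 && !is.null(a2_text) &&
        !any(grepl(paste0("^", unknown[1], "\t"), a2_lines)))
      stop(sprintf("reference error: event %s references unknown %s",
                   eid, unknown[1]), call. = FALSE)
  }
  if (length(dangling) > 0)
    warning(sprintf("dropping %d event(s) with dropped/cross-sentence parts: %s",
                    length(dangling), paste(dangling, collapse = ",")))
  ev_list <- list()
  for (eid in names(events)[alive]) {
    ev <- events[[eid]]
    kinds <- ifelse(grepl("^E", ev$fillers), "event", "entity")
    ev_list[[eid]] <- new_event(eid, ev$trigger_id, ev$roles, ev$fillers,
                                kinds, mods[[eid]] %||% "None")
  }
  # single-sentence scope: drop events whose participants live in
  # different sentences (and events depending on those, recursively)
  mention_sentence <- function(id) {
    df <- if (!is.null(entities) && id %in% entities$id) entities else triggers
    i <- match(id, df$id)
    span_to_tokens(tk$tokens, df$start[i], df$end[i])$sentence
  }
  repeat {
    bad <- character(0)
    for (eid in names(ev_list)) {
      ev <- ev_list[[eid]]
      sents <- mention_sentence(ev$trigger_id)
      for (k in seq_len(nrow(ev$args))) {
        fid <- ev$args$filler_id[k]
        if (ev$args$filler_kind[k] == "event") {
          if (!fid %in% names(ev_list)) { sents <- c(sents, NA); next }
          sents <- c(sents, mention_sentence(ev_list[[fid]]$trigger_id))
        } else sents <- c(sents, mention_sentence(fid))
      }
      if (anyNA(sents) || length(unique(sents)) > 1) bad <- c(bad, eid)
    }
    if (length(bad) == 0) break
    warning(sprintf("dropping %d cross-sentence event(s): %s",
                    length(bad), paste(bad, collapse = ",")))
    ev_list <- ev_list[setdiff(names(ev_list), bad)]
  }
  so_document(doc_id, txt_text, entities = entities, triggers = triggers,
              events = ev_list)
}

#' Serialize a document's triggers, events and modifications to .a2 text
#'
#' Identifiers are renumbered: trigger T-ids continue after the entity
#' T-ids, events are E1..En in topological order (sub-events first), and
#' M-lines follow. `read_standoff_document(write_standoff(doc))` yields an
#' event set isomorphic to `doc`'s.
#'
#' @param doc an `so_document`.
#' @return a2 file contents as a single string ("" when the document has
#'   no triggers and no events).
#' @export
write_standoff <- function(doc) {
  if (length(event_graph_cycle(doc$events)) > 0)
    stop("serialization error: event graph is cyclic", call. = FALSE)
  ent_nums <- suppressWarnings(as.integer(sub("^T", "", doc$entities$id)))
  next_t <- max(0L, ent_nums, na.rm = TRUE) + 1L
  lines <- character(0)
  tid_map <- character(0)
  if (nrow(doc$triggers) > 0) {
    for (i in seq_len(nrow(doc$triggers))) {
      new_id <- sprintf("T%d", next_t); next_t <- next_t + 1L
      tid_map[[doc$triggers$id[i]]] <- new_id
      lines <- c(lines, sprintf("%s\t%s %d %d\t%s", new_id,
                                doc$triggers$type[i], doc$triggers$start[i],
                                doc$triggers$end[i], doc$triggers$text[i]))
    }
  }
  # topological order over events (children first)
  order_ids <- character(0)
  placed <- character(0)
  pending <- names(doc$events)
  while (length(pending) > 0) {
    progressed <- FALSE
    for (eid in pending) {
      ev <- doc$events[[eid]]
      subs <- ev$args$filler_id[ev$args$filler_kind == "event"]
      if (all(subs %in% placed)) {
        order_ids <- c(order_ids, eid); placed <- c(placed, eid)
        progressed <- TRUE
      }
    }
    pending <- setdiff(pending, placed)
    if (!progressed) stop("serialization error: unresolvable event order")
  }
  eid_map <- setNames(sprintf("E%d", seq_along(order_ids)), order_ids)
  trig_type <- function(tid) doc$triggers$type[match(tid, doc$triggers$id)]
  for (eid in order_ids) {
    ev <- doc$events[[eid]]
    head <- sprintf("%s:%s", trig_type(ev$trigger_id), tid_map[[ev$trigger_id]])
    arg_str <- ""
    if (nrow(ev$args) > 0) {
      # number duplicate roles Theme, Theme2, ...
      roles <- ev$args$role
      suff <- stats::ave(seq_along(roles), roles, FUN = seq_along)
      roles_out <- ifelse(suff > 1, paste0(roles, suff), roles)
      fill_out <- ifelse(ev$args$filler_kind == "event",
                         eid_map[ev$args$filler_id],
                         ev$args$filler_id)
      arg_str <- paste0(" ", paste(roles_out, fill_out, sep = ":",
                                   collapse = " "))
    }
    lines <- c(lines, sprintf("%s\t%s%s", eid_map[[eid]], head, arg_str))
  }
  mi <- 1L
  for (eid in order_ids) {
    mod <- doc$events[[eid]]$modification
    if (!is.null(mod) && mod != "None") {
      lines <- c(lines, sprintf("M%d\t%s %s", mi, mod, eid_map[[eid]]))
      mi <- mi + 1L
    }
  }
  if (length(lines) == 0) "" else paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a standoff corpus directory
#'
#' Reads every `<id>.txt` with its companion `<id>.a1` and (if present)
#' `<id>.a2`.
#'
#' @param dir directory containing the standoff triples.
#' @return list of `so_document`.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0) stop("no .txt documents found in ", dir)
  lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    read_file <- function(p) if (file.exists(p))
      readChar(p, file.info(p)$size, useBytes = FALSE) else NULL
    read_standoff_document(read_file(tp), read_file(paste0(base, ".a1")),
                           read_file(paste0(base, ".a2")),
                           doc_id = basename(base))
  })
}

#' Write a standoff corpus directory
#' @param docs list of `so_document`.
#' @param dir output directory (created if needed).
#' @param write_a2 also write .a2 files (triggers/events/modifications).
#' @export
write_corpus <- function(docs, dir, write_a2 = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in docs) {
    base <- file.path(dir, doc$doc_id)
    writeLines(doc$text, paste0(base, ".txt"), sep = "")
    a1 <- if (nrow(doc$entities) > 0)
      paste0(paste(sprintf("%s\t%s %d %d\t%s", doc$entities$id,
                           doc$entities$type, doc$entities$start,
                           doc$entities$end, doc$entities$text),
                   collapse = "\n"), "\n") else ""
    writeLines(a1, paste0(base, ".a1"), sep = "")
    if (write_a2) writeLines(write_standoff(doc), paste0(base, ".a2"), sep = "")
  }
  invisible(dir)
}
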