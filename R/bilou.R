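# BILOU trigger-label codec.
#
# Label inventory: "O" plus {B-,I-,L-,U-} x event types. Encoding maps
# trigger token spans to labels; decoding is total — any label sequence,
# however ill-formed, is repaired deterministically: an orphan I opens a
# span like B, an orphan L becomes U, and a type conflict inside a span is
# resolved by the opening token's type.

#' BILOU label inventory for a schema
#'
#' @param schema an `event_schema`.
#' @return character vector: "O" first, then B-/I-/L-/U- per event type.
#' @export
bilou_labels <- function(schema) {
  types <- schema_event_types(schema)
  c("O", unlist(lapply(types, function(tt) paste0(c("B-", "I-", "L-", "U-"), tt))))
}

#' Encode trigger spans as a BILOU label sequence
#'
#' @param n_tokens number of tokens in the sentence.
#' @param trig_tok_start,trig_tok_end integer vectors of 1-based inclusive
#'   token spans, one per trigger.
#' @param trig_type character vector of event types, one per trigger.
#' @return character vector of `n_tokens` BILOU labels.
#' @export
encode_bilou <- function(n_tokens, trig_tok_start, trig_tok_end, trig_type) {
  labels <- rep("O", n_tokens)
  taken <- rep(FALSE, n_tokens)
  for (i in seq_along(trig_tok_start)) {
    s <- trig_tok_start[i]; e <- trig_tok_end[i]
    if (s < 1 || e > n_tokens || e < s)
      stop("trigger token span out of range")
    if (any(taken[s:e]))
      stop(sprintf("overlapping triggers at tokens %d..%d (type %s)",
                   s, e, trig_type[i]), call. = FALSE)
    taken[s:e] <- TRUE
    if (s == e) {
      labels[s] <- paste0("U-", trig_type[i])
    } else {
      labels[s] <- paste0("B-", trig_type[i])
      labels[e] <- paste0("L-", trig_type[i])
      if (e - s > 1) labels[(s + 1):(e - 1)] <- paste0("I-", trig_type[i])
    }
  }
  labels
}

#' Decode a BILOU label sequence into trigger spans
#'
#' Total on arbitrary input: ill-formed sequences are repaired (orphan I
#' opens a new span, orphan L emits a single-token span, a span left open
#' at an O/B/U/end closes at its last token; type conflicts resolve to the
#' opening token's type).
#'
#' @param labels character vector of BILOU labels.
#' @return data.frame with columns `tok_start`, `tok_end` (1-based
#'   inclusive) and `type`.
#' @export
decode_bilou <- function(labels) {
  out_s <- integer(0); out_e <- integer(0); out_t <- character(0)
  open_s <- NA_integer_; open_t <- NA_character_
  emit <- function(s, e, t) {
    out_s <<- c(out_s, s); out_e <<- c(out_e, e); out_t <<- c(out_t, t)
  }
  close_open <- function(last) {
    if (!is.na(open_s)) { emit(open_s, last, open_t); open_s <<- NA_integer_ }
  }
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (lb == "O" || !grepl("^[BILU]-", lb)) {
      close_open(i - 1L)
      next
    }
    tag <- substr(lb, 1, 1); tp <- substr(lb, 3, nchar(lb))
    if (tag == "U") {
      close_open(i - 1L); emit(i, i, tp)
    } else if (tag == "B") {
      close_open(i - 1L); open_s <- i; open_t <- tp
    } else if (tag == "I") {
      if (is.na(open_s)) { open_s <- i; open_t <- tp }  # orphan I -> B
    } else if (tag == "L") {
      if (is.na(open_s)) emit(i, i, tp)                 # orphan L -> U
      else close_open(i)
    }
  }
  close_open(length(labels))
  data.frame(tok_start = out_s, tok_end = out_e, type = out_t)
}

# Gold labels for a sentence; overlapping gold triggers keep the first by
# annotation order (single-label simplification), with a warning.
gold_bilou <- function(doc, sentence_index, labels_inventory) {
  tok_idx <- which(doc$tokens$sentence == sentence_index)
  tr <- doc$triggers[doc$triggers$sentence == sentence_index, , drop = FALSE]
  if (nrow(tr) > 0) {
    off <- min(tok_idx) - 1L
    keep <- rep(TRUE, nrow(tr))
    taken <- rep(FALSE, length(tok_idx))
    for (i in seq_len(nrow(tr))) {
      rng <- (tr$tok_start[i]:tr$tok_end[i]) - off
      if (any(taken[rng])) {
        keep[i] <- FALSE
        warning(sprintf("overlapping gold trigger %s dropped (single-label rule)",
                        tr$id[i]))
      } else taken[rng] <- TRUE
    }
    tr <- tr[keep, , drop = FALSE]
    lb <- encode_bilou(length(tok_idx), tr$tok_start - off, tr$tok_end - off,
                       tr$type)
  } else lb <- rep("O", length(tok_idx))
  match(lb, labels_inventory)
}
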