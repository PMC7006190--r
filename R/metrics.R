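# Corpus scoring: approximate span matching, approximate recursive event
# matching, precision/recall/F1, and the five-way extraction-error
# typology.

# extend a char span by one token on each side
extend_span <- function(tokens, start, end) {
  before <- tokens$end[tokens$end <= start]
  after <- tokens$start[tokens$start >= end]
  prev_tok <- tokens$start[tokens$end <= start]
  c(if (length(prev_tok)) max(prev_tok) else start,
    if (length(after)) {
      nxt <- min(after)
      cand <- tokens$end[tokens$start == nxt]
      max(cand)
    } else end)
}

#' Approximate span match
#'
#' TRUE when the predicted span lies within the gold span extended by one
#' token on each side (`strict = TRUE` requires identical spans).
#'
#' @param gold_span,pred_span length-2 integer vectors (0-based half-open
#'   char offsets).
#' @param tokens the document token table (for the one-token extension).
#' @param strict disable the extension.
#' @return logical.
#' @export
approximate_span_match <- function(gold_span, pred_span, tokens,
                                   strict = FALSE) {
  if (strict)
    return(gold_span[1] == pred_span[1] && gold_span[2] == pred_span[2])
  ext <- extend_span(tokens, gold_span[1], gold_span[2])
  pred_span[1] >= ext[1] && pred_span[2] <= ext[2]
}

trigger_match <- function(gold_doc, pred_doc, gid, pid, strict = FALSE) {
  g <- gold_doc$triggers[match(gid, gold_doc$triggers$id), ]
  p <- pred_doc$triggers[match(pid, pred_doc$triggers$id), ]
  g$type == p$type &&
    approximate_span_match(c(g$start, g$end), c(p$start, p$end),
                           gold_doc$tokens, strict = strict)
}

#' Approximate recursive event match
#'
#' TRUE iff the triggers approximately match with equal event type, the
#' argument multisets align role by role, entity fillers agree on span and
#' type, and event fillers match recursively.
#'
#' @param gold_doc,pred_doc the documents owning the two events.
#' @param gold_ev,pred_ev event records.
#' @param strict require exact trigger spans.
#' @return logical.
#' @export
event_match <- function(gold_doc, pred_doc, gold_ev, pred_ev,
                        strict = FALSE) {
  if (!trigger_match(gold_doc, pred_doc, gold_ev$trigger_id,
                     pred_ev$trigger_id, strict)) return(FALSE)
  ga <- gold_ev$args; pa <- pred_ev$args
  if (nrow(ga) != nrow(pa)) return(FALSE)
  if (nrow(ga) == 0) return(TRUE)
  arg_ok <- function(gi, pi) {
    if (ga$role[gi] != pa$role[pi]) return(FALSE)
    if (ga$filler_kind[gi] != pa$filler_kind[pi]) return(FALSE)
    if (ga$filler_kind[gi] == "entity") {
      ge <- gold_doc$entities[match(ga$filler_id[gi], gold_doc$entities$id), ]
      pe <- pred_doc$entities[match(pa$filler_id[pi], pred_doc$entities$id), ]
      ge$type == pe$type && ge$start == pe$start && ge$end == pe$end
    } else {
      event_match(gold_doc, pred_doc,
                  gold_doc$events[[ga$filler_id[gi]]],
                  pred_doc$events[[pa$filler_id[pi]]], strict)
    }
  }
  # backtracking bipartite alignment (argument counts are tiny)
  try_align <- function(gis, pis) {
    if (length(gis) == 0) return(TRUE)
    for (k in seq_along(pis)) {
      if (arg_ok(gis[1], pis[k]) && try_align(gis[-1], pis[-k]))
        return(TRUE)
    }
    FALSE
  }
  try_align(seq_len(nrow(ga)), seq_len(nrow(pa)))
}

#' Score a predicted corpus against gold
#'
#' Greedy 1-1 matching of predicted to gold events per document (each gold
#' event matched at most once) under approximate span and recursive
#' matching. Precision = TP/predicted, recall = TP/gold, F1 = 2PR/(P+R)
#' (0 when P+R = 0; zero predictions give P = 0 by convention).
#'
#' @param gold_docs,pred_docs lists of `so_document` with aligned doc_ids.
#' @param strict require exact trigger spans.
#' @return list of class `score_report`: `overall` (data.frame with tp,
#'   n_gold, n_pred, recall, precision, f1) and `by_type`.
#' @export
score_corpus <- function(gold_docs, pred_docs, strict = FALSE) {
  gids <- vapply(gold_docs, `[[`, "", "doc_id")
  pids <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!identical(sort(gids), sort(pids)))
    stop("misaligned corpora: document ids differ", call. = FALSE)
  pred_docs <- pred_docs[match(gids, pids)]
  ev_type <- function(doc, ev) doc$triggers$type[match(ev$trigger_id, doc$triggers$id)]
  tally <- list()
  bump <- function(type, what) {
    row <- tally[[type]] %||% c(tp = 0, gold = 0, pred = 0)
    row[what] <- row[what] + 1
    tally[[type]] <<- row
  }
  match_flags <- list()
  for (d in seq_along(gold_docs)) {
    gd <- gold_docs[[d]]; pd <- pred_docs[[d]]
    for (ev in gd$events) bump(ev_type(gd, ev), "gold")
    gold_used <- rep(FALSE, length(gd$events))
    doc_flags <- setNames(rep(FALSE, length(pd$events)), names(pd$events))
    for (pid in names(pd$events)) {
      pe <- pd$events[[pid]]
      bump(ev_type(pd, pe), "pred")
      for (gi in seq_along(gd$events)) {
        if (gold_used[gi]) next
        if (event_match(gd, pd, gd$events[[gi]], pe, strict)) {
          gold_used[gi] <- TRUE
          doc_flags[[pid]] <- TRUE
          bump(ev_type(pd, pe), "tp")
          break
        }
      }
    }
    match_flags[[gd$doc_id]] <- list(pred_matched = doc_flags,
                                     gold_matched = gold_used)
  }
  mk <- function(m) {
    tp <- m["tp"]; ng <- m["gold"]; np <- m["pred"]
    p <- if (np > 0) tp / np else 0
    r <- if (ng > 0) tp / ng else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(tp = tp, n_gold = ng, n_pred = np, recall = r,
               precision = p, f1 = f, row.names = NULL)
  }
  total <- Reduce(`+`, tally, c(tp = 0, gold = 0, pred = 0))
  by_type <- do.call(rbind, lapply(names(tally), function(tt)
    cbind(type = tt, mk(tally[[tt]]))))
  structure(list(overall = mk(total), by_type = by_type,
                 match_flags = match_flags),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("events: gold %d, predicted %d, matched %d\n",
              x$overall$n_gold, x$overall$n_pred, x$overall$tp))
  cat(sprintf("recall %.4f  precision %.4f  F1 %.4f\n",
              x$overall$recall, x$overall$precision, x$overall$f1))
  invisible(x)
}

#' Five-way extraction-error breakdown
#'
#' Classifies each unmatched predicted event and each missed gold event
#' (not double-counting gold events whose trigger is shared with a
#' classified false positive) into exactly one of: wrong trigger span
#' (including spurious/missed triggers), wrong trigger label, redundant
#' arguments, wrong arguments, or other; precedence in that order.
#'
#' @param gold_docs,pred_docs lists of aligned `so_document`.
#' @return data.frame of counts and fractions per category (fractions over
#'   the gold + spurious event denominator).
#' @export
classify_errors <- function(gold_docs, pred_docs) {
  rep_ <- score_corpus(gold_docs, pred_docs)
  cats <- c("wrong_trigger_span", "wrong_trigger_label", "redundant_args",
            "wrong_args", "other")
  cnt <- setNames(numeric(5), cats)
  gids <- vapply(gold_docs, `[[`, "", "doc_id")
  pids <- vapply(pred_docs, `[[`, "", "doc_id")
  pred_docs <- pred_docs[match(gids, pids)]
  n_events <- 0
  for (d in seq_along(gold_docs)) {
    gd <- gold_docs[[d]]; pd <- pred_docs[[d]]
    flags <- rep_$match_flags[[gd$doc_id]]
    n_events <- n_events + length(gd$events) +
      sum(!flags$pred_matched)  # gold + spurious denominator
    covered_gold_triggers <- character(0)
    for (pid in names(pd$events)) {
      if (isTRUE(flags$pred_matched[[pid]])) next
      pe <- pd$events[[pid]]
      pt <- pd$triggers[match(pe$trigger_id, pd$triggers$id), ]
      # gold triggers approximately overlapping the predicted one
      span_ok <- vapply(seq_len(nrow(gd$triggers)), function(gi)
        approximate_span_match(
          c(gd$triggers$start[gi], gd$triggers$end[gi]),
          c(pt$start, pt$end), gd$tokens), TRUE)
      if (!any(span_ok)) {
        cnt["wrong_trigger_span"] <- cnt["wrong_trigger_span"] + 1
        next
      }
      type_ok <- span_ok & gd$triggers$type == pt$type
      if (!any(type_ok)) {
        cnt["wrong_trigger_label"] <- cnt["wrong_trigger_label"] + 1
        covered_gold_triggers <- c(covered_gold_triggers,
                                   gd$triggers$id[span_ok])
        next
      }
      covered_gold_triggers <- c(covered_gold_triggers,
                                 gd$triggers$id[type_ok])
      # trigger fine: argument-level error
      gevs <- Filter(function(ev) ev$trigger_id %in% gd$triggers$id[type_ok],
                     gd$events)
      if (length(gevs) == 0) {
        cnt["other"] <- cnt["other"] + 1
        next
      }
      superset <- any(vapply(gevs, function(gev) {
        nrow(pe$args) > nrow(gev$args) &&
          all(paste(gev$args$role, gev$args$filler_id) %in%
                paste(pe$args$role, pe$args$filler_id))
      }, TRUE))
      if (superset) cnt["redundant_args"] <- cnt["redundant_args"] + 1
      else cnt["wrong_args"] <- cnt["wrong_args"] + 1
    }
    # missed gold events whose trigger no classified FP accounts for
    for (gi in seq_along(gd$events)) {
      if (flags$gold_matched[gi]) next
      gev <- gd$events[[gi]]
      if (gev$trigger_id %in% covered_gold_triggers) next
      gt <- gd$triggers[match(gev$trigger_id, gd$triggers$id), ]
      span_ok <- vapply(seq_len(nrow(pd$triggers)), function(pi)
        approximate_span_match(c(gt$start, gt$end),
                               c(pd$triggers$start[pi], pd$triggers$end[pi]),
                               gd$tokens), TRUE)
      if (!any(span_ok))
        cnt["wrong_trigger_span"] <- cnt["wrong_trigger_span"] + 1
      else if (!any(span_ok & pd$triggers$type == gt$type))
        cnt["wrong_trigger_label"] <- cnt["wrong_trigger_label"] + 1
      else cnt["wrong_args"] <- cnt["wrong_args"] + 1
    }
  }
  data.frame(category = cats, count = as.numeric(cnt),
             fraction = if (n_events > 0) as.numeric(cnt) / n_events
                        else rep(0, 5))
}
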