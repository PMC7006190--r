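# Combination strategy: choose the subset of candidate events minimising
# the support-lacking / support-waste penalty. Greedy best-improvement
# selection (O(|C|^2) penalty evaluations) with a brute-force oracle for
# small instances, topological ordering of nested candidates, an event
# loop detector and modification assignment.

#' Support bundle for the combination strategy
#'
#' @param trigger_support numeric; support of each detected trigger.
#' @param relation_support numeric; support of each emitted relation.
#' @param cand_support numeric; support s_e of each candidate event.
#' @param cand_trigger integer; the trigger each candidate belongs to.
#' @param cand_rels list of integer vectors; the relations each candidate
#'   consumes.
#' @param cand_filler_triggers list of integer vectors; triggers used as
#'   nested event fillers by each candidate (empty when flat).
#' @return list of class `support_bundle`.
#' @export
support_bundle <- function(trigger_support, relation_support, cand_support,
                           cand_trigger, cand_rels,
                           cand_filler_triggers = NULL) {
  nc <- length(cand_support)
  stopifnot(length(cand_trigger) == nc, length(cand_rels) == nc)
  if (is.null(cand_filler_triggers))
    cand_filler_triggers <- rep(list(integer(0)), nc)
  if (nc > 0 && (max(c(0L, cand_trigger)) > length(trigger_support) ||
                 max(c(0L, unlist(cand_rels))) > length(relation_support)))
    stop("candidate references a trigger/relation missing from the bundle")
  structure(list(trigger_support = trigger_support,
                 relation_support = relation_support,
                 cand_support = cand_support, cand_trigger = cand_trigger,
                 cand_rels = cand_rels,
                 cand_filler_triggers = cand_filler_triggers),
            class = "support_bundle")
}

#' Penalty of a candidate-event subset
#'
#' `sum over chosen events of max(1 - alpha * s_e, 0)` (support lacking)
#' plus `beta * sum` of positive supports of triggers covered by no chosen
#' event plus `gamma * sum` of positive supports of uncovered relations
#' (support waste). Negative supports contribute no waste.
#'
#' @param chosen integer vector of candidate indices (subset of the
#'   bundle's candidates).
#' @param bundle a [support_bundle()].
#' @param alpha,beta,gamma non-negative penalty weights.
#' @return the penalty (a single number).
#' @export
penalty_score <- function(chosen, bundle, alpha = 0.5, beta = 0.25,
                          gamma = 0.125) {
  if (length(chosen) > 0 &&
      (min(chosen) < 1 || max(chosen) > length(bundle$cand_support)))
    stop("chosen event not present in the bundle")
  lacking <- sum(pmax(1 - alpha * bundle$cand_support[chosen], 0))
  cov_t <- unique(bundle$cand_trigger[chosen])
  cov_r <- unique(unlist(bundle$cand_rels[chosen]))
  waste_t <- sum(pmax(bundle$trigger_support[setdiff(
    seq_along(bundle$trigger_support), cov_t)], 0))
  waste_r <- sum(pmax(bundle$relation_support[setdiff(
    seq_along(bundle$relation_support), cov_r)], 0))
  lacking + beta * waste_t + gamma * waste_r
}

#' Exact minimiser of the selection penalty (oracle)
#'
#' Enumerates all subsets of the candidate set; intended as a testing
#' oracle for small instances only. Ties break toward smaller subsets,
#' then lexicographic candidate order.
#'
#' @inheritParams penalty_score
#' @param bundle a [support_bundle()].
#' @return list with `chosen` (sorted indices) and `penalty`.
#' @export
select_events_bruteforce <- function(bundle, alpha = 0.5, beta = 0.25,
                                     gamma = 0.125) {
  nc <- length(bundle$cand_support)
  if (nc > 20) stop("brute-force selection refuses |C| > 20")
  best <- integer(0)
  best_pen <- penalty_score(integer(0), bundle, alpha, beta, gamma)
  lex_less <- function(a, b) {
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    length(a) < length(b)
  }
  if (nc > 0) for (mask in 1:(2^nc - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(nc - 1))) > 0)
    pen <- penalty_score(sel, bundle, alpha, beta, gamma)
    if (pen < best_pen - 1e-12) {
      best <- sel; best_pen <- pen
    } else if (abs(pen - best_pen) <= 1e-12) {
      if (length(sel) < length(best) ||
          (length(sel) == length(best) && lex_less(sel, best))) {
        best <- sel; best_pen <- pen
      }
    }
  }
  list(chosen = best, penalty = best_pen)
}

#' Greedy approximate minimiser of the selection penalty
#'
#' Starting from the empty set, repeatedly adds the candidate whose
#' inclusion yields the largest penalty decrease, stopping when no
#' inclusion decreases the penalty. Candidates are considered in
#' topological order of their nested structure (children first; ties in
#' gain break toward the earlier candidate in that order), and a candidate
#' with nested event fillers is addable only once each filler trigger has
#' a chosen event, so a chosen child's support is available to its parent.
#'
#' @inheritParams penalty_score
#' @param bundle a [support_bundle()].
#' @return list with `chosen` (indices in the order added) and `penalty`
#'   (which always equals `penalty_score(chosen, bundle, ...)`).
#' @export
select_events_greedy <- function(bundle, alpha = 0.5, beta = 0.25,
                                 gamma = 0.125) {
  ord <- topological_sort_candidates(bundle)
  chosen <- integer(0)
  cur <- penalty_score(chosen, bundle, alpha, beta, gamma)
  remaining <- ord
  repeat {
    chosen_trigs <- unique(bundle$cand_trigger[chosen])
    addable <- remaining[vapply(remaining, function(j)
      all(bundle$cand_filler_triggers[[j]] %in% chosen_trigs), TRUE)]
    if (length(addable) == 0) break
    pens <- vapply(addable, function(j)
      penalty_score(c(chosen, j), bundle, alpha, beta, gamma), 0)
    gains <- cur - pens
    # a zero-gain inclusion is still beneficial when the candidate's own
    # support-lacking term vanishes (alpha * s_e >= 1): the event is
    # confidently valid and costs nothing
    free_ride <- abs(gains) <= 1e-12 &
      alpha * bundle$cand_support[addable] >= 1
    eligible <- which(gains > 1e-12 | free_ride)
    if (length(eligible) == 0) break
    k <- eligible[which_max1(gains[eligible])]
    chosen <- c(chosen, addable[k])
    cur <- pens[k]
    remaining <- setdiff(remaining, addable[k])
  }
  list(chosen = chosen, penalty = cur)
}

#' Topological candidate order (children first)
#'
#' Orders candidate indices so that candidates of triggers used as nested
#' fillers precede the candidates that use them. Cyclic trigger-level
#' nesting is broken by removing the cycle edge with the lowest relation
#' support (with a warning). Stable: without nesting the input order is
#' preserved.
#'
#' @param bundle a [support_bundle()].
#' @return integer vector: a permutation of the candidate indices.
#' @export
topological_sort_candidates <- function(bundle) {
  nc <- length(bundle$cand_support)
  if (nc == 0) return(integer(0))
  # trigger-level edges parent -> child with the max support of any
  # relation realising the nesting
  edges <- list()
  for (j in seq_len(nc)) {
    p <- bundle$cand_trigger[j]
    for (ch in bundle$cand_filler_triggers[[j]]) {
      key <- paste(p, ch)
      sup <- max(bundle$relation_support[bundle$cand_rels[[j]]], -Inf)
      if (is.null(edges[[key]]) || edges[[key]]$sup < sup)
        edges[[key]] <- list(p = p, ch = ch, sup = sup)
    }
  }
  trigs <- sort(unique(bundle$cand_trigger))
  depth <- setNames(rep(NA_integer_, length(trigs)), trigs)
  repeat {
    kids <- vapply(edges, function(e) e$ch, 0L)
    pars <- vapply(edges, function(e) e$p, 0L)
    # children-first depth: triggers with no outgoing (parent) edges are 0
    depth[] <- NA_integer_
    ok <- TRUE
    assign_depth <- function(tg, seen = integer(0)) {
      if (tg %in% seen) return(NA_integer_)   # cycle
      if (!is.na(depth[[as.character(tg)]]))
        return(depth[[as.character(tg)]])
      ch <- kids[pars == tg]
      d <- if (length(ch) == 0) 0L else {
        ds <- vapply(ch, assign_depth, 0L, seen = c(seen, tg))
        if (anyNA(ds)) return(NA_integer_)
        max(ds) + 1L
      }
      depth[[as.character(tg)]] <<- d
      d
    }
    for (tg in trigs) assign_depth(tg)
    if (!anyNA(depth)) break
    # break the lowest-support edge on some cycle
    sups <- vapply(edges, function(e) e$sup, 0)
    drop_key <- names(edges)[which.min(sups)]
    warning(sprintf("cyclic trigger nesting: dropping edge %s (support %.3g)",
                    drop_key, edges[[drop_key]]$sup))
    edges[[drop_key]] <- NULL
  }
  cand_depth <- depth[as.character(bundle$cand_trigger)]
  order(cand_depth, seq_len(nc))
}

#' Discard events that would close a loop
#'
#' Events are added one by one in the given order; an event whose
#' event-valued fillers would create a cycle (including self-reference) in
#' the filler graph is dropped. The output graph is acyclic.
#'
#' @param events list of event records (each with `id` and `args` holding
#'   `filler_id`/`filler_kind`).
#' @return the kept events, in input order.
#' @export
detect_and_discard_loops <- function(events) {
  kept <- list()
  reach <- list()  # event id -> ids reachable through fillers
  for (ev in events) {
    subs <- ev$args$filler_id[ev$args$filler_kind == "event"]
    closes <- ev$id %in% subs ||
      any(vapply(subs, function(s) ev$id %in% (reach[[s]] %||% character(0)) ||
                   s == ev$id, TRUE))
    if (closes) next
    kept[[ev$id]] <- ev
    reach[[ev$id]] <- unique(c(subs, unlist(reach[subs])))
    # update ancestors' reach
    for (k in names(reach))
      if (ev$id %in% reach[[k]])
        reach[[k]] <- unique(c(reach[[k]], reach[[ev$id]]))
  }
  unname(kept)
}

#' Assign Negation/Speculation/None modifications
#'
#' Each event's modification is the argmax of its log-probability triple
#' `p_m` (Negation, Speculation, None); ties resolve to None.
#'
#' @param events list of event records.
#' @param logp_mods list (or matrix rows) of length-3 log-probability
#'   vectors aligned with `events`.
#' @return the events with `modification` set.
#' @export
assign_modifications <- function(events, logp_mods) {
  labs <- c("Negation", "Speculation", "None")
  for (i in seq_along(events)) {
    pm <- logp_mods[[i]]
    events[[i]]$modification <-
      if (pm[3] >= max(pm[1:2])) "None" else labs[which_max1(pm[1:2])]
  }
  events
}
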