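# Event evaluation surface: schema-constrained enumeration of candidate
# event structures, role-label sequences, validity/modification scoring
# with a second BiLSTM, and training-time undersampling.

#' Enumerate schema-valid candidate events for detected triggers
#'
#' For each trigger, every subset of its outgoing relations whose role
#' counts satisfy the schema's min/max constraints (and whose filler
#' categories are admissible) becomes one candidate. Enumeration is capped
#' per trigger, keeping combinations built from the highest-support
#' relations first. Relations pointing at other triggers yield nested
#' candidates (the role binds the sub-event's trigger; the sub-event's own
#' argument choice is resolved by the combination strategy).
#'
#' @param triggers data.frame of detected triggers (`tok_start`,
#'   `tok_end`, `type`, `support`).
#' @param relations data.frame with `src` (trigger row), `role`,
#'   `dst_kind` ("trigger"/"entity"), `dst` (row index), `support`, and
#'   `filler_type`.
#' @param schema an `event_schema`.
#' @param cap maximum candidates per trigger.
#' @return list of candidates: each has `trigger` (row), `rel_idx`
#'   (row indices into `relations`), `args` (the corresponding rows).
#' @export
enumerate_candidate_events <- function(triggers, relations, schema,
                                       cap = 128L) {
  out <- list()
  for (ti in seq_len(nrow(triggers))) {
    et <- triggers$type[ti]
    decl <- schema$event_types[[et]]
    if (is.null(decl)) next
    ridx <- which(relations$src == ti &
                    vapply(seq_len(nrow(relations)), function(j)
                      relations$src[j] == ti &&
                        schema_allows(schema, et, relations$role[j],
                                      relations$filler_type[j]), TRUE))
    ridx <- ridx[order(-relations$support[ridx])]
    max_rel <- 14L  # 2^14 subsets is the enumeration bound
    if (length(ridx) > max_rel) {
      warning(sprintf("trigger %d: %d relations, keeping top %d by support",
                      ti, length(ridx), max_rel))
      ridx <- ridx[seq_len(max_rel)]
    }
    m <- length(ridx)
    cands <- list()
    for (mask in 0:(2^m - 1)) {
      sel <- ridx[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0]
      roles <- relations$role[sel]
      if (!schema_counts_ok(schema, et, roles)) next
      cands[[length(cands) + 1L]] <- list(
        trigger = ti, rel_idx = sel,
        args = relations[sel, , drop = FALSE],
        total_support = sum(relations$support[sel]))
    }
    if (length(cands) > cap) {
      warning(sprintf("trigger %d: candidate cap %d applied", ti, cap))
      ord <- order(-vapply(cands, `[[`, 0, "total_support"))
      cands <- cands[ord[seq_len(cap)]]
    }
    out <- c(out, cands)
  }
  out
}

#' Role-label sequence of a candidate event
#'
#' Every token is labelled "none" except the candidate's trigger tokens
#' ("event_trigger") and each argument filler's tokens (its role; for a
#' nested argument, the sub-event's trigger tokens carry the role).
#' Overlaps resolve by the precedence event_trigger > role > none, and
#' between two roles the earlier argument wins.
#'
#' @param cand one candidate from [enumerate_candidate_events()].
#' @param n sentence length in tokens.
#' @param triggers,entities mention tables giving filler token spans.
#' @return character vector of n role labels.
#' @export
role_label_sequence <- function(cand, n, triggers, entities) {
  lab <- rep("none", n)
  args <- cand$args
  for (j in seq_len(nrow(args))) {
    sp <- if (args$dst_kind[j] == "trigger")
      triggers[args$dst[j], ] else entities[args$dst[j], ]
    if (sp$tok_start < 1 || sp$tok_end > n)
      stop("argument span outside sentence", call. = FALSE)
    rng <- sp$tok_start:sp$tok_end
    lab[rng][lab[rng] == "none"] <- args$role[j]
  }
  tr <- triggers[cand$trigger, ]
  lab[tr$tok_start:tr$tok_end] <- "event_trigger"
  lab
}

#' Score a candidate event's validity and modification
#'
#' Embeds the candidate's role-label sequence, concatenates it with the
#' encoder states, entity-label and trigger-label embeddings, runs the
#' event-evaluation BiLSTM, and maps the concatenated final states of the
#' two directions to a validity log-probability pair `p_e` and a
#' modification log-probability triple `p_m` (Negation, Speculation,
#' None). The support value is `s_e = p_e[1] - p_e[2]`.
#'
#' @param model an `evex_model`.
#' @param enc sentence encoding; `trig` the trigger prediction.
#' @param role_labels character role-label sequence (length n).
#' @return list `p_e`, `p_m`, `s_e`.
#' @export
evaluate_event <- function(model, enc, trig, role_labels) {
  role_ids <- match(role_labels, model$vocab$role_labels)
  if (anyNA(role_ids)) stop("unknown role label", call. = FALSE)
  fwd <- ee_forward(model$params, model$control, enc$H, enc$E, trig$T,
                    role_ids)
  list(p_e = fwd$pval, p_m = fwd$pmod, s_e = fwd$s_e)
}

#' Undersample negative candidate events for training
#'
#' Per sentence, negatives are downsampled to the positive count (one
#' negative is kept when there are no positives). Deterministic given the
#' seed; the caller's RNG state is restored.
#'
#' @param is_positive logical vector over candidates.
#' @param seed integer seed.
#' @return integer indices of the kept candidates (positives first).
#' @export
undersample_negatives <- function(is_positive, seed) {
  pos <- which(is_positive); neg <- which(!is_positive)
  keep_n <- min(length(neg), max(1L, length(pos)))
  if (length(neg) == 0) keep_n <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kept_neg <- if (keep_n > 0) sort(sample(neg, keep_n)) else integer(0)
  c(pos, kept_neg)
}
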