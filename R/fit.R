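# Joint end-to-end training of the shared encoder with the trigger,
# relation and event heads, plus prediction orchestration (ensemble
# averaging of per-class log-probabilities, combination-strategy event
# assembly, loop detection, modification assignment).

# ---- per-sentence static preparation ----------------------------------

# local (sentence) views of triggers/entities with 1-based token spans
localize_mentions <- function(df, tok_off) {
  if (nrow(df) == 0) return(cbind(df[0, ], data.frame()))
  df$tok_start <- df$tok_start - tok_off
  df$tok_end <- df$tok_end - tok_off
  df
}

prepare_sentence <- function(doc, si, vocab, schema, ctl) {
  tok_idx <- which(doc$tokens$sentence == si)
  if (length(tok_idx) == 0) return(NULL)
  off <- min(tok_idx) - 1L
  texts <- doc$tokens$text[tok_idx]
  ent_local <- localize_mentions(
    doc$entities[doc$entities$sentence == si, , drop = FALSE], off)
  trig_all <- doc$triggers[doc$triggers$sentence == si, , drop = FALSE]
  # single-label rule: overlapping gold triggers keep the first
  keep <- rep(TRUE, nrow(trig_all))
  taken <- rep(FALSE, length(tok_idx))
  for (i in seq_len(nrow(trig_all))) {
    rng <- (trig_all$tok_start[i]:trig_all$tok_end[i]) - off
    if (any(taken[rng])) keep[i] <- FALSE else taken[rng] <- TRUE
  }
  trig_local <- localize_mentions(trig_all[keep, , drop = FALSE], off)
  gold_ids <- match(
    encode_bilou(length(tok_idx), trig_local$tok_start, trig_local$tok_end,
                 trig_local$type),
    vocab$bilou)

  # gold relations: one row per (event trigger -> filler mention)
  rel_rows <- list()
  ev_rel_sets <- list()   # event id -> relation row indices
  ev_meta <- list()
  for (eid in names(doc$events)) {
    ev <- doc$events[[eid]]
    srow <- match(ev$trigger_id, trig_local$id)
    if (is.na(srow)) next
    ridx <- integer(0)
    ok <- TRUE
    for (k in seq_len(nrow(ev$args))) {
      fid <- ev$args$filler_id[k]
      if (ev$args$filler_kind[k] == "entity") {
        drow <- match(fid, ent_local$id); dkind <- "entity"
        ftype <- ent_local$type[drow]
      } else {
        sub_tr <- doc$events[[fid]]$trigger_id
        drow <- match(sub_tr, trig_local$id); dkind <- "trigger"
        ftype <- trig_local$type[drow]
      }
      if (is.na(drow)) { ok <- FALSE; break }
      key <- paste(srow, dkind, drow, ev$args$role[k])
      hit <- which(vapply(rel_rows, function(r) r$key == key, TRUE))
      if (length(hit) == 0) {
        rel_rows[[length(rel_rows) + 1L]] <- list(
          key = key, src = srow, role = ev$args$role[k], dst_kind = dkind,
          dst = drow, filler_type = ftype)
        hit <- length(rel_rows)
      }
      ridx <- c(ridx, hit)
    }
    if (ok) {
      ev_rel_sets[[eid]] <- sort(ridx)
      ev_meta[[eid]] <- list(mod = ev$modification, trigger = srow)
    }
  }
  gold_rels <- if (length(rel_rows) > 0) data.frame(
    src = vapply(rel_rows, `[[`, 0L, "src"),
    role = vapply(rel_rows, `[[`, "", "role"),
    dst_kind = vapply(rel_rows, `[[`, "", "dst_kind"),
    dst = vapply(rel_rows, `[[`, 0L, "dst"),
    filler_type = vapply(rel_rows, `[[`, "", "filler_type"),
    support = 0) else data.frame(
      src = integer(0), role = character(0), dst_kind = character(0),
      dst = integer(0), filler_type = character(0), support = numeric(0))

  # candidate pairs among gold triggers + entities, with gold role labels
  pairs <- generate_candidate_pairs(trig_local, ent_local)
  pair_gold <- rep(1L, nrow(pairs))
  if (nrow(pairs) > 0 && nrow(gold_rels) > 0) {
    pk <- paste(pairs$src, pairs$dst_kind, pairs$dst)
    gk <- paste(gold_rels$src, gold_rels$dst_kind, gold_rels$dst)
    hit <- match(pk, gk)
    pair_gold[!is.na(hit)] <-
      match(gold_rels$role[hit[!is.na(hit)]], vocab$relations)
  }

  # candidate events from gold relations; positives match a gold arg set
  cands <- enumerate_candidate_events(trig_local, gold_rels, schema,
                                      cap = ctl$candidate_cap)
  cand_pos <- logical(length(cands))
  cand_mod <- rep(3L, length(cands))  # None
  mod_levels <- c("Negation", "Speculation", "None")
  for (ci in seq_along(cands)) {
    sel <- sort(as.integer(cands[[ci]]$rel_idx))
    for (eid in names(ev_rel_sets)) {
      if (cands[[ci]]$trigger == ev_meta[[eid]]$trigger &&
          identical(sel, as.integer(ev_rel_sets[[eid]]))) {
        cand_pos[ci] <- TRUE
        cand_mod[ci] <- match(ev_meta[[eid]]$mod, mod_levels)
        break
      }
    }
  }
  cand_roles <- lapply(cands, function(cd)
    match(role_label_sequence(cd, length(tok_idx), trig_local, ent_local),
          vocab$role_labels))

  list(si = si, n = length(tok_idx), texts = texts,
       wids = word_id(vocab, texts),
       char_ids = lapply(texts, char_ids, vocab = vocab),
       ent_ids = entity_label_ids(doc, si, vocab),
       gold_ids = gold_ids, trig_local = trig_local, ent_local = ent_local,
       pairs = pairs, pair_gold = pair_gold,
       cands = cands, cand_pos = cand_pos, cand_mod = cand_mod,
       cand_roles = cand_roles)
}

# ---- loss --------------------------------------------------------------

weighted_nll <- function(lp_rows, gold, w) {
  if (length(gold) == 0) return(0)
  nll <- -vapply(seq_along(gold), function(i) lp_rows[[i]][gold[i]], 0)
  sum(w * nll) / length(gold)
}

#' Joint negative log-likelihood of a batch
#'
#' Sum of the four head losses (trigger, relation, event validity, event
#' modification). Each head's loss is the class-weighted NLL averaged
#' within a sentence, then averaged over the batch's sentences (sentences
#' with no items for a head contribute zero). Trigger/relation positives
#' (non-none gold classes) carry `class_weight`; negatives weight 1.
#'
#' @param batch list of per-sentence prediction/gold lists with fields
#'   `tr_logp` (n x K matrix), `tr_gold`, `rc_logp` (list of vectors),
#'   `rc_gold`, `ee_val_logp`, `ee_val_gold`, `ee_mod_logp`, `ee_mod_gold`.
#' @param class_weight positive-class weight for TR and RC.
#' @return list with per-head means `tr`, `rc`, `ee_val`, `ee_mod` and
#'   their sum `total`.
#' @export
joint_loss <- function(batch, class_weight = 5) {
  acc <- c(tr = 0, rc = 0, ee_val = 0, ee_mod = 0)
  for (s in batch) {
    acc["tr"] <- acc["tr"] + weighted_nll(
      lapply(seq_len(nrow(s$tr_logp)), function(i) s$tr_logp[i, ]),
      s$tr_gold, ifelse(s$tr_gold != 1L, class_weight, 1))
    acc["rc"] <- acc["rc"] + weighted_nll(
      s$rc_logp, s$rc_gold, ifelse(s$rc_gold != 1L, class_weight, 1))
    acc["ee_val"] <- acc["ee_val"] + weighted_nll(
      s$ee_val_logp, s$ee_val_gold, rep(1, length(s$ee_val_gold)))
    acc["ee_mod"] <- acc["ee_mod"] + weighted_nll(
      s$ee_mod_logp, s$ee_mod_gold, rep(1, length(s$ee_mod_gold)))
  }
  acc <- acc / length(batch)
  c(as.list(acc), list(total = sum(acc)))
}

# ---- one training sentence: forward, loss, backward -------------------

train_sentence <- function(P, G, ctl, vocab, schema, sd, eps, scale) {
  cw <- ctl$class_weight
  enc <- encoder_forward(P, ctl, vocab, sd$texts, sd$char_ids, sd$wids,
                         sd$ent_ids, train = TRUE)
  trf <- tr_forward(P, ctl, vocab, enc$H, mode = "train",
                    gold_ids = sd$gold_ids, eps = eps)
  n <- sd$n
  w_tr <- ifelse(sd$gold_ids != 1L, cw, 1)
  loss_tr <- weighted_nll(lapply(seq_len(n), function(i) trf$LP[i, ]),
                          sd$gold_ids, w_tr)
  dLP <- matrix(0, n, ncol(trf$LP))
  dLP[cbind(seq_len(n), sd$gold_ids)] <- -w_tr / n * scale

  hd2 <- 2 * ctl$hidden
  M <- cbind(enc$H, trf$T, enc$E)
  dM <- matrix(0, nrow(M), ncol(M))
  loss_rc <- 0
  np <- nrow(sd$pairs)
  if (np > 0) {
    w_rc <- ifelse(sd$pair_gold != 1L, cw, 1)
    for (j in seq_len(np)) {
      geo <- pair_geometry(sd$pairs$s1[j], sd$pairs$e1[j],
                           sd$pairs$s2[j], sd$pairs$e2[j])
      fwd <- rc_forward_pair(P, ctl, M, geo)
      loss_rc <- loss_rc + w_rc[j] * (-fwd$lp[sd$pair_gold[j]]) / np
      dlp <- rep(0, length(fwd$lp))
      dlp[sd$pair_gold[j]] <- -w_rc[j] / np * scale
      dM <- rc_backward_pair(dlp, fwd, P, ctl, G, dM)
    }
  }

  loss_ev <- 0; loss_em <- 0
  dH_ee <- matrix(0, n, hd2)
  dE_ee <- matrix(0, n, ctl$entity_dim)
  dT_ee <- matrix(0, n, ctl$trig_emb)
  nc <- length(sd$cands)
  if (nc > 0) {
    pos <- which(sd$cand_pos); neg <- which(!sd$cand_pos)
    keep_neg <- if (length(neg) > 0)
      sample(neg, min(length(neg), max(1L, length(pos)))) else integer(0)
    kept <- c(pos, keep_neg)
    nk <- length(kept)
    npos <- length(pos)
    for (ci in kept) {
      fwd <- ee_forward(P, ctl, enc$H, enc$E, trf$T, sd$cand_roles[[ci]])
      vlab <- if (sd$cand_pos[ci]) 1L else 2L
      loss_ev <- loss_ev + (-fwd$pval[vlab]) / nk
      dpv <- rep(0, 2); dpv[vlab] <- -1 / nk * scale
      dpm <- rep(0, 3)
      if (sd$cand_pos[ci]) {
        loss_em <- loss_em + (-fwd$pmod[sd$cand_mod[ci]]) / npos
        dpm[sd$cand_mod[ci]] <- -1 / npos * scale
      }
      bb <- ee_backward(dpv, dpm, fwd, P, ctl, G)
      dH_ee <- dH_ee + bb$dH; dE_ee <- dE_ee + bb$dE; dT_ee <- dT_ee + bb$dT
    }
  }

  # combine gradient flows into the shared encoder
  dH_rc <- dM[, 1:hd2, drop = FALSE]
  dT_rc <- dM[, (hd2 + 1):(hd2 + ctl$trig_emb), drop = FALSE]
  dE_rc <- dM[, (hd2 + ctl$trig_emb + 1):ncol(dM), drop = FALSE]
  dH_tr <- tr_backward(dLP, dT_rc + dT_ee, trf, P, ctl, G)
  G$P$W_ent <- accum_rows(G$P$W_ent, sd$ent_ids, dE_rc + dE_ee)
  encoder_backward(dH_tr + dH_rc + dH_ee, enc, P, ctl, G)

  c(tr = loss_tr, rc = loss_rc, ee_val = loss_ev, ee_mod = loss_em)
}

# ---- fitting -----------------------------------------------------------

#' Fit the joint event-extraction model
#'
#' Trains the shared encoder and the trigger/relation/event heads jointly
#' by minimising the summed NLL of all four heads (gradients from every
#' head flow into the shared encoder within one forward pass per
#' sentence). Uses Adam, Xavier initialisation, scheduled sampling for the
#' trigger head's previous-label feedback, per-sentence undersampling of
#' negative candidate events, LSTM-output dropout and classic L2 weight
#' decay. With `ensemble_size > 1`, trains that many members from distinct
#' seeds; prediction averages their per-class log-probabilities.
#'
#' @param corpus list of `so_document` with gold annotation, or a
#'   directory of standoff files.
#' @param schema an `event_schema`.
#' @param control an [evex_control()] list.
#' @param verbose print per-epoch losses.
#' @return An object of class `evex_model` with elements `params` (first
#'   member's parameters), `members` (all ensemble members), `vocab`,
#'   `schema`, `control` and `losses` (per-epoch head losses, cf. the
#'   loss-ordering diagnostic).
#' @export
evex_fit <- function(corpus, schema, control = evex_control(),
                     verbose = FALSE) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  ctl <- control
  vocab <- build_vocab(corpus, schema)
  sents <- list()
  for (doc in corpus)
    for (si in seq_len(nrow(doc$sentences))) {
      sd <- prepare_sentence(doc, si, vocab, schema, ctl)
      if (!is.null(sd) && sd$n > 0) sents[[length(sents) + 1L]] <- sd
    }
  if (length(sents) == 0) stop("empty corpus", call. = FALSE)

  members <- vector("list", ctl$ensemble_size)
  losses_all <- vector("list", ctl$ensemble_size)
  for (mi in seq_len(ctl$ensemble_size)) {
    set.seed(ctl$seed + 1000L * (mi - 1L))
    P <- init_params(vocab, ctl)
    opt <- adam_init(P)
    ep_losses <- matrix(0, ctl$epochs, 4,
                        dimnames = list(NULL, c("tr", "rc", "ee_val", "ee_mod")))
    for (epoch in seq_len(ctl$epochs) - 1L) {
      eps <- scheduled_sampling_prob(epoch, ctl$ss_k)
      ord <- sample(length(sents))
      tot <- c(tr = 0, rc = 0, ee_val = 0, ee_mod = 0)
      for (b0 in seq(1, length(ord), by = ctl$batch_size)) {
        bidx <- ord[b0:min(b0 + ctl$batch_size - 1L, length(ord))]
        G <- new_grad_env(P)
        scale <- 1 / length(bidx)
        for (sid in bidx)
          tot <- tot + train_sentence(P, G, ctl, vocab, schema,
                                      sents[[sid]], eps, scale)
        st <- adam_step(P, G$P, opt, ctl$lr, ctl$weight_decay)
        P <- st$P; opt <- st$state
      }
      ep_losses[epoch + 1L, ] <- tot / length(sents)
      if (verbose)
        message(sprintf("member %d epoch %d: tr %.4f rc %.4f ee %.4f mod %.4f",
                        mi, epoch, ep_losses[epoch + 1, 1],
                        ep_losses[epoch + 1, 2], ep_losses[epoch + 1, 3],
                        ep_losses[epoch + 1, 4]))
    }
    members[[mi]] <- P
    losses_all[[mi]] <- as.data.frame(ep_losses)
  }
  structure(list(params = members[[1]], members = members, vocab = vocab,
                 schema = schema, control = ctl,
                 losses = losses_all[[1]], losses_members = losses_all),
            class = "evex_model")
}

#' Average per-class log-probabilities across ensemble members
#'
#' @param lps list of aligned numeric vectors/matrices (one per member).
#' @return their element-wise arithmetic mean.
#' @export
ensemble_combine <- function(lps) Reduce(`+`, lps) / length(lps)

# ---- prediction --------------------------------------------------------

# multi-model greedy trigger pass: the combined (averaged) log-probability
# decides each label, and that label's embedding (per member) feeds the
# next step of every member
tr_forward_multi <- function(members, ctl, vocab, Hs, threshold) {
  n <- nrow(Hs[[1]])
  nlab <- length(vocab$bilou)
  t0 <- nlab + 1L
  nm <- length(members)
  LP <- matrix(0, n, nlab)
  fed <- integer(n); margins <- rep(NA_real_, n)
  Ts <- lapply(members, function(P) matrix(0, n, ctl$trig_emb))
  prev_id <- t0
  for (i in seq_len(n)) {
    lp_m <- lapply(seq_len(nm), function(m) {
      P <- members[[m]]
      x <- c(Hs[[m]][i, ], P$T_emb[prev_id, ])
      log_softmax(mlp2_forward(x, P$W2, P$b2, P$W3, P$b3)$y)
    })
    lp <- ensemble_combine(lp_m)
    best <- which_max1(lp[-1]) + 1L
    margin <- lp[best] - lp[1]
    assigned <- if (margin > threshold) best else 1L
    LP[i, ] <- lp; fed[i] <- assigned
    margins[i] <- if (assigned != 1L) lp[assigned] - lp[1] else margin
    for (m in seq_len(nm)) Ts[[m]][i, ] <- members[[m]]$T_emb[assigned, ]
    prev_id <- assigned
  }
  list(LP = LP, fed = fed, margins = margins, Ts = Ts)
}

predict_sentence <- function(model, doc, si, mode, thr_t, thr_r) {
  ctl <- model$control; vocab <- model$vocab; schema <- model$schema
  tok_idx <- which(doc$tokens$sentence == si)
  if (length(tok_idx) == 0) return(NULL)
  off <- min(tok_idx) - 1L
  texts <- doc$tokens$text[tok_idx]
  ent_ids <- entity_label_ids(doc, si, vocab)
  ent_local <- localize_mentions(
    doc$entities[doc$entities$sentence == si, , drop = FALSE], off)
  members <- model$members
  encs <- lapply(members, function(P)
    encoder_forward(P, ctl, vocab, texts, lapply(texts, char_ids, vocab = vocab),
                    word_id(vocab, texts), ent_ids, train = FALSE))
  Hs <- lapply(encs, `[[`, "H")
  trf <- tr_forward_multi(members, ctl, vocab, Hs, thr_t)
  labels <- vocab$bilou[trf$fed]
  trig <- decode_bilou(labels)
  if (nrow(trig) > 0)
    trig$support <- vapply(seq_len(nrow(trig)), function(j)
      mean(trf$margins[trig$tok_start[j]:trig$tok_end[j]]), 0)
  trig$text <- vapply(seq_len(nrow(trig)), function(j)
    paste(texts[trig$tok_start[j]:trig$tok_end[j]], collapse = " "), "")

  pairs <- generate_candidate_pairs(trig, ent_local)
  rel_rows <- list()
  if (nrow(pairs) > 0) {
    Ms <- lapply(seq_along(members), function(m)
      cbind(Hs[[m]], trf$Ts[[m]], encs[[m]]$E))
    for (j in seq_len(nrow(pairs))) {
      geo <- pair_geometry(pairs$s1[j], pairs$e1[j], pairs$s2[j], pairs$e2[j])
      lp <- ensemble_combine(lapply(seq_along(members), function(m)
        rc_forward_pair(members[[m]], ctl, Ms[[m]], geo)$lp))
      ftype <- if (pairs$dst_kind[j] == "trigger")
        trig$type[pairs$dst[j]] else ent_local$type[pairs$dst[j]]
      dec <- decide_relation(lp, vocab, src_type = trig$type[pairs$src[j]],
                             filler_type = ftype, schema = schema,
                             threshold_r = thr_r)
      if (dec$type != "none")
        rel_rows[[length(rel_rows) + 1L]] <- data.frame(
          src = pairs$src[j], role = dec$type,
          dst_kind = pairs$dst_kind[j], dst = pairs$dst[j],
          filler_type = ftype, support = dec$support)
    }
  }
  rels <- if (length(rel_rows) > 0) do.call(rbind, rel_rows) else
    data.frame(src = integer(0), role = character(0),
               dst_kind = character(0), dst = integer(0),
               filler_type = character(0), support = numeric(0))

  cands <- enumerate_candidate_events(trig, rels, schema,
                                      cap = ctl$candidate_cap)
  ee <- lapply(cands, function(cd) {
    role_ids <- match(role_label_sequence(cd, length(texts), trig, ent_local),
                      vocab$role_labels)
    pv <- ensemble_combine(lapply(seq_along(members), function(m)
      ee_forward(members[[m]], ctl, Hs[[m]], encs[[m]]$E, trf$Ts[[m]],
                 role_ids)$pval))
    pm <- ensemble_combine(lapply(seq_along(members), function(m)
      ee_forward(members[[m]], ctl, Hs[[m]], encs[[m]]$E, trf$Ts[[m]],
                 role_ids)$pmod))
    list(pval = pv, pmod = pm, s_e = pv[1] - pv[2])
  })

  list(off = off, texts = texts, trig = trig, ent_local = ent_local,
       rels = rels, cands = cands, ee = ee)
}

# choose candidate subset according to the assembly mode
assemble_events <- function(sp, ctl, mode) {
  cands <- sp$cands
  if (length(cands) == 0) return(integer(0))
  s_e <- vapply(sp$ee, `[[`, 0, "s_e")
  bundle <- support_bundle(
    trigger_support = sp$trig$support,
    relation_support = sp$rels$support,
    cand_support = s_e,
    cand_trigger = vapply(cands, `[[`, 0L, "trigger"),
    cand_rels = lapply(cands, `[[`, "rel_idx"),
    cand_filler_triggers = lapply(cands, function(cd) {
      k <- cd$args$dst_kind == "trigger"
      unique(cd$args$dst[k])
    }))
  chosen <- switch(mode,
    "cs" = , "zero-threshold" =
      select_events_greedy(bundle, ctl$alpha, ctl$beta, ctl$gamma)$chosen,
    "rule-all" = seq_along(cands),
    "rule-single" = {
      # one event per trigger: most arguments, then highest relation support
      trigs <- vapply(cands, `[[`, 0L, "trigger")
      unlist(lapply(unique(trigs), function(tg) {
        idx <- which(trigs == tg)
        nargs <- vapply(idx, function(j) length(cands[[j]]$rel_idx), 0L)
        sup <- vapply(idx, function(j)
          sum(sp$rels$support[cands[[j]]$rel_idx]), 0)
        idx[order(-nargs, -sup)[1]]
      }))
    },
    "ee-probability" = which(s_e > 0))
  # realizability: nested fillers must have a chosen event on their trigger
  repeat {
    chosen_trigs <- unique(vapply(cands[chosen], `[[`, 0L, "trigger"))
    ok <- vapply(chosen, function(j)
      all(bundle$cand_filler_triggers[[j]] %in% chosen_trigs), TRUE)
    if (all(ok)) break
    chosen <- chosen[ok]
  }
  chosen
}

#' Predict events for one document
#'
#' Runs, per sentence: encoder, trigger recognition, relation
#' classification, candidate enumeration, event evaluation, the selected
#' assembly mode (combination strategy by default), the loop detector and
#' modification assignment. Ensemble members are combined by averaging
#' per-class log-probabilities before threshold/support logic.
#'
#' @param model an `evex_model`.
#' @param doc an `so_document` (gold entities are used; gold
#'   triggers/events ignored).
#' @param mode assembly mode; defaults to the model's control.
#' @return An `so_document` carrying the predicted triggers and events.
#' @export
predict_document <- function(model, doc, mode = model$control$mode) {
  ctl <- model$control
  thr_t <- if (mode %in% c("zero-threshold", "ee-probability")) 0 else ctl$threshold_t
  thr_r <- if (mode %in% c("zero-threshold", "ee-probability")) 0 else ctl$threshold_r
  trig_rows <- list(); events <- list()
  ent_count <- nrow(doc$entities)
  for (si in seq_len(nrow(doc$sentences))) {
    sp <- predict_sentence(model, doc, si, mode, thr_t, thr_r)
    if (is.null(sp)) next
    chosen <- assemble_events(sp, ctl, mode)
    if (length(chosen) == 0) next
    # bind nested args to the chosen event (max s_e) of the filler trigger
    ev_of_trigger <- list()
    for (j in chosen) {
      tg <- sp$cands[[j]]$trigger
      s <- sp$ee[[j]]$s_e
      cur <- ev_of_trigger[[as.character(tg)]]
      if (is.null(cur) || cur$s < s)
        ev_of_trigger[[as.character(tg)]] <- list(j = j, s = s)
    }
    tok <- doc$tokens[doc$tokens$sentence == si, , drop = FALSE]
    reg_trigger <- function(tg) {
      key <- paste(si, tg)
      if (is.null(trig_rows[[key]])) {
        trig_rows[[key]] <<- data.frame(
          id = NA_character_, type = sp$trig$type[tg],
          start = tok$start[sp$trig$tok_start[tg]],
          end = tok$end[sp$trig$tok_end[tg]],
          text = slice_text(doc$text, tok$start[sp$trig$tok_start[tg]],
                            tok$end[sp$trig$tok_end[tg]]))
      }
      key
    }
    j_pos <- list()
    base <- length(events)
    for (k in seq_along(chosen)) j_pos[[as.character(chosen[k])]] <- k
    new_events <- list()
    for (k in seq_along(chosen)) {
      j <- chosen[k]
      cd <- sp$cands[[j]]
      tkey <- reg_trigger(cd$trigger)
      roles <- cd$args$role
      kinds <- ifelse(cd$args$dst_kind == "trigger", "event", "entity")
      fids <- vapply(seq_len(nrow(cd$args)), function(a) {
        if (cd$args$dst_kind[a] == "trigger") {
          tgt <- ev_of_trigger[[as.character(cd$args$dst[a])]]$j
          sprintf("E%d", base + j_pos[[as.character(tgt)]])
        } else sp$ent_local$id[cd$args$dst[a]]
      }, "")
      eid <- sprintf("E%d", base + k)
      new_events[[eid]] <- c(new_event(eid, tkey, roles, fids, kinds),
                             list(pmod = sp$ee[[j]]$pmod))
    }
    # order children before parents so the loop detector sees a DAG-safe
    # insertion order, then drop loop-closing events
    new_events <- detect_and_discard_loops(new_events)
    names(new_events) <- vapply(new_events, `[[`, "", "id")
    # prune events whose nested filler got dropped by the loop detector
    repeat {
      ok <- vapply(new_events, function(ev)
        all(ev$args$filler_id[ev$args$filler_kind == "event"] %in%
              names(new_events)), TRUE)
      if (all(ok)) break
      new_events <- new_events[ok]
    }
    new_events <- assign_modifications(new_events,
                                       lapply(new_events, `[[`, "pmod"))
    events <- c(events, new_events)
  }
  # materialise trigger table with doc-wide ids
  trig_df <- NULL
  if (length(trig_rows) > 0) {
    trig_df <- do.call(rbind, trig_rows)
    trig_df$id <- sprintf("T%d", ent_count + seq_len(nrow(trig_df)))
    key_to_id <- setNames(trig_df$id, names(trig_rows))
  }
  # swap trigger keys for ids, renumber event ids doc-wide, keep only
  # triggers actually referenced
  used_keys <- character(0)
  ev_final <- list()
  for (eid in names(events)) {
    ev <- events[[eid]]
    used_keys <- c(used_keys, ev$trigger_id)
    ev$trigger_id <- key_to_id[[ev$trigger_id]]
    ev$pmod <- NULL
    ev_final[[eid]] <- ev
  }
  if (!is.null(trig_df)) {
    keep <- names(trig_rows) %in% used_keys
    trig_df <- trig_df[keep, , drop = FALSE]
  }
  so_document(doc$doc_id, doc$text, entities = doc$entities,
              triggers = trig_df, events = ev_final)
}

#' @export
#' @rdname predict_document
#' @param object an `evex_model`.
#' @param newdata list of `so_document` or a standoff directory.
#' @param ... unused.
predict.evex_model <- function(object, newdata,
                               mode = object$control$mode, ...) {
  if (is.character(newdata)) newdata <- read_corpus(newdata)
  lapply(newdata, function(d) predict_document(object, d, mode = mode))
}

# ---- S3 methods --------------------------------------------------------

#' @export
print.evex_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, 0L))
  cat(sprintf("Joint event-extraction model: %d parameters/member, %d member(s)\n",
              np, length(x$members)))
  cat(sprintf("schema: %d event types; vocabulary: %d words\n",
              length(x$schema$event_types), length(x$vocab$words)))
  cat(sprintf("final losses: tr %.4f rc %.4f ee %.4f mod %.4f\n",
              utils::tail(x$losses$tr, 1), utils::tail(x$losses$rc, 1),
              utils::tail(x$losses$ee_val, 1),
              utils::tail(x$losses$ee_mod, 1)))
  invisible(x)
}

#' @export
summary.evex_model <- function(object, ...) {
  print(object)
  cat("\ncontrol:\n")
  ctl <- object$control
  cat(sprintf("  hidden %d, epochs %d, lr %g, batch %d, dropout %g\n",
              ctl$hidden, ctl$epochs, ctl$lr, ctl$batch_size, ctl$dropout))
  cat(sprintf("  thresholds t/r %g/%g, penalty %g/%g/%g, mode %s\n",
              ctl$threshold_t, ctl$threshold_r, ctl$alpha, ctl$beta,
              ctl$gamma, ctl$mode))
  invisible(object)
}

#' @export
coef.evex_model <- function(object, ...) {
  fl <- flatten_params(object$params)
  vapply(fl, function(x) sqrt(mean(x^2)), 0)   # per-block RMS summary
}

#' @export
plot.evex_model <- function(x, ...) {
  L <- x$losses
  graphics::matplot(seq_len(nrow(L)), as.matrix(L), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = colnames(L), lty = 1,
                   col = seq_len(ncol(L)))
  invisible(x)
}
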