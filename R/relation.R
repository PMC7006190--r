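# Relation classification surface: candidate pair generation, pooled
# src/mid/dst segment features with a distance embedding, and thresholded
# role assignment with schema post-filtering.

#' Generate candidate argument pairs within a sentence
#'
#' All ordered trigger->trigger pairs (both directions, no self-pairs) and
#' all trigger->entity pairs. Token spans are 1-based inclusive local
#' (sentence) coordinates.
#'
#' @param triggers data.frame with `tok_start`, `tok_end`, `type` (one row
#'   per detected trigger).
#' @param entities data.frame with `tok_start`, `tok_end`, `type`.
#' @return data.frame with columns `src` (trigger row), `dst_kind`
#'   ("trigger"/"entity"), `dst` (row index in the respective table),
#'   spans `s1,e1,s2,e2`, `dist` (token distance start2 - end1 in text
#'   order, floored at 0) and `dir` (1 when the source trigger follows its
#'   partner in the text).
#' @export
generate_candidate_pairs <- function(triggers, entities) {
  nt <- nrow(triggers); ne <- nrow(entities)
  rows <- list()
  for (i in seq_len(nt)) {
    partners <- rbind(
      if (nt > 1) data.frame(dst_kind = "trigger",
                             dst = setdiff(seq_len(nt), i)),
      if (ne > 0) data.frame(dst_kind = "entity", dst = seq_len(ne)))
    if (is.null(partners)) next
    for (j in seq_len(nrow(partners))) {
      d <- if (partners$dst_kind[j] == "trigger")
        triggers[partners$dst[j], ] else entities[partners$dst[j], ]
      geo <- pair_geometry(triggers$tok_start[i], triggers$tok_end[i],
                           d$tok_start, d$tok_end)
      rows[[length(rows) + 1L]] <- data.frame(
        src = i, dst_kind = partners$dst_kind[j], dst = partners$dst[j],
        s1 = triggers$tok_start[i], e1 = triggers$tok_end[i],
        s2 = d$tok_start, e2 = d$tok_end,
        dist = max(0L, geo$b[1] - geo$a[2]), dir = geo$dir)
    }
  }
  if (length(rows) == 0)
    return(data.frame(src = integer(0), dst_kind = character(0),
                      dst = integer(0), s1 = integer(0), e1 = integer(0),
                      s2 = integer(0), e2 = integer(0), dist = integer(0),
                      dir = integer(0)))
  do.call(rbind, rows)
}

#' Build pooled segment features for one candidate pair
#'
#' Concatenates channel-wise max pooling over the `[H, T, E]` slices of
#' the two mentions (taken in text order, with a binary direction flag),
#' a convolution + max pooling over the between-segment (a learned
#' adjacency vector when the mentions are adjacent or overlap), and an
#' embedding of the clipped token distance.
#'
#' @param model an `evex_model`.
#' @param enc sentence encoding from [encode_sentence()].
#' @param trig trigger prediction from [recognize_triggers()] (supplies T).
#' @param pair one row of [generate_candidate_pairs()] output.
#' @return list with the feature vector `r` and the forward cache.
#' @export
build_pair_features <- function(model, enc, trig, pair) {
  n <- nrow(enc$H)
  if (min(pair$s1, pair$s2) < 1 || max(pair$e1, pair$e2) > n)
    stop("pair span outside sentence", call. = FALSE)
  M <- cbind(enc$H, trig$T, enc$E)
  geo <- pair_geometry(pair$s1, pair$e1, pair$s2, pair$e2)
  fwd <- rc_forward_pair(model$params, model$control, M, geo)
  list(r = fwd$cache$m2$x, lp = fwd$lp, cache = fwd$cache, geo = geo)
}

#' Classify one candidate pair into an argument role
#'
#' Scores the pair features through the relation head; the best non-none
#' role is assigned when its log-probability margin over none exceeds
#' `threshold_r`, otherwise none. Roles the schema does not allow for the
#' source trigger's event type (with the partner's category as filler) are
#' post-filtered to none.
#'
#' @param model an `evex_model`.
#' @param enc,trig,pair as in [build_pair_features()].
#' @param filler_type entity/event type of the partner mention (for the
#'   schema post-filter); NULL skips the filter.
#' @param threshold_r margin threshold.
#' @return list with `type` (role or "none"), `logp`, `support`.
#' @export
classify_relation <- function(model, enc, trig, pair, filler_type = NULL,
                              threshold_r = model$control$threshold_r) {
  ft <- build_pair_features(model, enc, trig, pair)
  decide_relation(ft$lp, model$vocab,
                  src_type = trig$triggers$type[pair$src],
                  filler_type = filler_type, schema = model$schema,
                  threshold_r = threshold_r)
}

# thresholded assignment + schema post-filter on an RC log-prob vector
decide_relation <- function(lp, vocab, src_type = NULL, filler_type = NULL,
                            schema = NULL, threshold_r) {
  best <- which_max1(lp[-1]) + 1L
  margin <- lp[best] - lp[1]
  type <- if (margin > threshold_r) vocab$relations[best] else "none"
  if (type != "none" && !is.null(schema) && !is.null(src_type) &&
      !schema_allows(schema, src_type, type, filler_type))
    type <- "none"
  list(type = type, logp = lp, support = margin)
}
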