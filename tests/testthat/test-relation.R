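mk_mentions <- function(spans, types) {
  data.frame(tok_start = vapply(spans, `[`, 0, 1),
             tok_end = vapply(spans, `[`, 0, 2),
             type = types)
}

test_that("candidate pair generation is ordered, self-free and complete", {
  trig <- mk_mentions(list(c(2, 2), c(5, 5)), c("Expression", "Regulation"))
  ents <- mk_mentions(list(c(1, 1), c(3, 3), c(7, 7)),
                      c("Gene", "Gene", "Disease"))
  pairs <- generate_candidate_pairs(trig, ents)
  expect_equal(nrow(pairs), 2 * (1 + 3))  # both trigger orders + entities
  expect_true(all(pairs$src %in% 1:2))
  expect_false(any(pairs$dst_kind == "trigger" & pairs$src == pairs$dst))
  # both orders of the trigger-trigger pair are present
  tt <- pairs[pairs$dst_kind == "trigger", ]
  expect_setequal(paste(tt$src, tt$dst), c("1 2", "2 1"))

  expect_equal(nrow(generate_candidate_pairs(trig[0, ], ents)), 0)
  expect_equal(nrow(generate_candidate_pairs(trig[1, , drop = FALSE],
                                             ents[0, ])), 0)
})

docs_rc <- generate_corpus(3, cfg = synthetic_config(seed = 8))

test_that("pair features: adjacency vector, distance clipping, fixed width", {
  m <- raw_model(docs_rc, hidden = 6, dist_clip = 30)
  toks <- rep(c("We", "observed", "grk1", "levels", "that", "tlr4", "."), 5)[1:32]
  enc <- encode_sentence(m, toks)
  trig <- recognize_triggers(m, enc, threshold_t = -Inf)
  mk <- function(s1, e1, s2, e2)
    data.frame(src = 1, dst_kind = "entity", dst = 1,
               s1 = s1, e1 = e1, s2 = s2, e2 = e2,
               dist = max(0, s2 - e1), dir = as.integer(s1 > s2))
  # adjacent mentions: the mid feature slot is exactly the learned vector
  ft_adj <- build_pair_features(m, enc, trig, mk(2, 2, 3, 3))
  S <- 2 * m$control$hidden + m$control$trig_emb + m$control$entity_dim
  mc <- m$control$mid_channels
  expect_equal(ft_adj$r[(S + 1):(S + mc)], m$params$mid_adj)
  # distance beyond the clip maps to the clip's embedding row
  ft_far <- build_pair_features(m, enc, trig, mk(1, 1, 32, 32))
  ft_clip <- build_pair_features(m, enc, trig, mk(1, 1, 31, 31))
  dslice <- (2 * S + mc + 1):(2 * S + mc + m$control$dist_dim)
  expect_equal(ft_far$r[dslice], ft_clip$r[dslice])
  # identical spans on two calls give identical features (determinism)
  expect_identical(build_pair_features(m, enc, trig, mk(2, 2, 6, 7))$r,
                   build_pair_features(m, enc, trig, mk(2, 2, 6, 7))$r)
  # feature width is constant across geometries
  widths <- vapply(list(mk(1, 2, 4, 4), mk(9, 9, 2, 3), mk(1, 1, 2, 2),
                        mk(5, 8, 20, 25)), function(p)
    length(build_pair_features(m, enc, trig, p)$r), 0)
  expect_equal(length(unique(widths)), 1L)
  # spans outside the sentence error
  expect_error(build_pair_features(m, enc, trig, mk(1, 1, 40, 40)),
               "outside")
})

test_that("relation decision rule: margin threshold, ties, schema filter", {
  vocab <- list(relations = c("none", "Cause", "Theme"))
  # p_m = -0.2 vs p_none = -1.9: margin 1.7 > -2 -> class assigned
  lp <- c(-1.9, -0.2, -3)
  lp <- lp - bioevex:::logsumexp(lp)
  d <- bioevex:::decide_relation(lp, vocab, threshold_r = -2)
  expect_equal(d$type, "Cause")
  expect_equal(d$support, lp[2] - lp[1])
  # uniform log-probs: margin 0 > -2, argmax tie broken to lowest index
  lpu <- log(rep(1 / 3, 3))
  expect_equal(bioevex:::decide_relation(lpu, vocab, threshold_r = -2)$type,
               "Cause")
  # +Inf threshold silences everything
  expect_equal(bioevex:::decide_relation(lp, vocab, threshold_r = Inf)$type,
               "none")
  # schema post-filter: Cause is not a role of Expression
  d2 <- bioevex:::decide_relation(lp, vocab, src_type = "Expression",
                                  filler_type = "Gene", schema = toy_schema(),
                                  threshold_r = -2)
  expect_equal(d2$type, "none")
})

test_that("lowering threshold_r never decreases the emitted relation count", {
  tm <- toy_model()
  m <- tm$model
  # first training sentence that yields at least one candidate pair
  pairs <- NULL
  for (doc in tm$docs) {
    toks <- doc$tokens$text[doc$tokens$sentence == 1]
    ents <- m$vocab$entity_labels[bioevex:::entity_label_ids(doc, 1, m$vocab)]
    enc <- encode_sentence(m, toks, ents)
    trig <- recognize_triggers(m, enc, threshold_t = -4)
    ent_local <- bioevex:::localize_mentions(
      doc$entities[doc$entities$sentence == 1, , drop = FALSE], 0L)
    pairs <- generate_candidate_pairs(trig$triggers, ent_local)
    if (nrow(pairs) > 0) break
  }
  expect_gt(nrow(pairs), 0)
  counts <- vapply(seq(4, -4, by = -1), function(th) {
    sum(vapply(seq_len(nrow(pairs)), function(j) {
      ft <- if (pairs$dst_kind[j] == "trigger")
        trig$triggers$type[pairs$dst[j]] else ent_local$type[pairs$dst[j]]
      classify_relation(m, enc, trig, pairs[j, ], filler_type = ft,
                        threshold_r = th)$type != "none"
    }, TRUE))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})
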