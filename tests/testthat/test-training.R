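test_that("joint loss matches hand arithmetic and is linear in class weights", {
  lp1 <- log(matrix(c(0.7, 0.2, 0.1,
                      0.1, 0.8, 0.1), 2, 3, byrow = TRUE))
  s <- list(tr_logp = lp1, tr_gold = c(1L, 2L),
            rc_logp = list(log(c(0.6, 0.4))), rc_gold = 2L,
            ee_val_logp = list(log(c(0.9, 0.1))), ee_val_gold = 1L,
            ee_mod_logp = list(log(c(0.2, 0.2, 0.6))), ee_mod_gold = 3L)
  jl <- joint_loss(list(s), class_weight = 5)
  # TR: mean of [1 * -log .7, 5 * -log .8]; RC: 5 * -log .4
  expect_equal(jl$tr, (-log(0.7) + 5 * -log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(jl$rc, 5 * -log(0.4), tolerance = 1e-12)
  expect_equal(jl$ee_val, -log(0.9), tolerance = 1e-12)
  expect_equal(jl$ee_mod, -log(0.6), tolerance = 1e-12)
  expect_equal(jl$total, jl$tr + jl$rc + jl$ee_val + jl$ee_mod)
  # doubling all class weights doubles the weighted terms' contributions
  jl2 <- joint_loss(list(s), class_weight = 10)
  expect_equal(jl2$rc, 2 * jl$rc, tolerance = 1e-12)
  # perfect one-hot predictions drive the loss to zero
  sp <- list(tr_logp = log(matrix(c(1 - 1e-12, 1e-12), 1)), tr_gold = 1L,
             rc_logp = list(), rc_gold = integer(0),
             ee_val_logp = list(), ee_val_gold = integer(0),
             ee_mod_logp = list(), ee_mod_gold = integer(0))
  expect_lt(joint_loss(list(sp))$total, 1e-10)
})

test_that("training is seed-deterministic end to end", {
  docs <- generate_corpus(4, cfg = synthetic_config(seed = 17))
  ctl <- evex_control(hidden = 6, char_channels = 4, tr_hidden = 8,
                      rc_hidden = 8, ee_hidden = 6, epochs = 3, seed = 21)
  m1 <- evex_fit(docs, toy_schema(), ctl)
  m2 <- evex_fit(docs, toy_schema(), ctl)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$losses, m2$losses)
})

test_that("every head's gradient reaches the shared encoder", {
  schema <- toy_schema()
  docs <- generate_corpus(3, cfg = synthetic_config(seed = 23,
                                                    event_density = 1.8))
  ctl <- evex_control(hidden = 4, word_dim = 4, entity_dim = 2,
                      char_dim = 2, char_channels = 3, trig_emb = 2,
                      role_emb = 2, dist_dim = 2, mid_channels = 2,
                      tr_hidden = 4, rc_hidden = 4, ee_hidden = 3,
                      dropout = 0, seed = 2)
  vocab <- bioevex:::build_vocab(docs, schema)
  set.seed(2)
  P <- bioevex:::init_params(vocab, ctl)
  sd <- NULL
  for (doc in docs) for (si in seq_len(nrow(doc$sentences))) {
    cand <- bioevex:::prepare_sentence(doc, si, vocab, schema, ctl)
    if (!is.null(cand) && length(cand$cands) > 0 &&
        nrow(cand$pairs) > 0) { sd <- cand; break }
  }
  expect_false(is.null(sd))
  # gradients with EE candidates vs. with EE candidates removed: the
  # encoder parameters feel the difference, so parameter sharing is real
  grads_for <- function(sd) {
    G <- bioevex:::new_grad_env(P)
    set.seed(42)
    bioevex:::train_sentence(P, G, ctl, vocab, schema, sd, eps = 1,
                             scale = 1)
    G$P$enc1_f$Wx
  }
  sd_noee <- sd
  sd_noee$cands <- list(); sd_noee$cand_pos <- logical(0)
  sd_noee$cand_roles <- list()
  g_full <- grads_for(sd)
  g_noee <- grads_for(sd_noee)
  expect_gt(max(abs(g_full)), 0)
  expect_gt(max(abs(g_full - g_noee)), 1e-8)
  # likewise for the relation head
  sd_norc <- sd
  sd_norc$pairs <- sd$pairs[0, , drop = FALSE]
  sd_norc$pair_gold <- integer(0)
  g_norc <- grads_for(sd_norc)
  expect_gt(max(abs(g_full - g_norc)), 1e-8)
})

test_that("ensembles combine by log-probability averaging", {
  # identity on identical members
  lp <- log(c(0.3, 0.7))
  expect_equal(ensemble_combine(list(lp, lp, lp)), lp)
  # symmetric opposite margins cancel
  a <- c(1, -1); b <- c(-1, 1)
  expect_equal(ensemble_combine(list(a, b)), c(0, 0))
  # monotone in each member
  expect_true(all(ensemble_combine(list(a + 0.5, b)) >=
                    ensemble_combine(list(a, b))))
})

test_that("an ensemble of identical members predicts like the single model", {
  tm <- toy_model()
  m <- tm$model
  m3 <- m
  m3$members <- list(m$params, m$params, m$params)
  doc <- tm$docs[[1]]
  p1 <- predict_document(m, doc)
  p3 <- predict_document(m3, doc)
  expect_equal(score_corpus(list(p1), list(p3), strict = TRUE)$overall$f1,
               if (length(p1$events) > 0) 1 else 0)
  expect_equal(length(p1$events), length(p3$events))
})

test_that("ensemble training yields distinct members", {
  docs <- generate_corpus(3, cfg = synthetic_config(seed = 29))
  ctl <- evex_control(hidden = 4, char_channels = 3, tr_hidden = 6,
                      rc_hidden = 6, ee_hidden = 4, epochs = 2,
                      ensemble_size = 2, seed = 31)
  m <- evex_fit(docs, toy_schema(), ctl)
  expect_length(m$members, 2)
  expect_gt(max(abs(m$members[[1]]$W2 - m$members[[2]]$W2)), 1e-6)
})

test_that("prediction on a document with no entities and no triggers is empty", {
  tm <- toy_model()
  doc <- so_document("blank", "Nothing eventful happens here today.")
  pred <- predict_document(tm$model, doc)
  expect_length(pred$events, 0)
})

test_that("predicted documents round trip through standoff and never violate schema", {
  tm <- toy_model()
  preds <- predict(tm$model, tm$docs[1:4])
  for (pd in preds) {
    expect_length(validate_events(pd, toy_schema()), 0)
    expect_length(bioevex:::event_graph_cycle(pd$events), 0)
    a1 <- if (nrow(pd$entities) > 0)
      paste0(paste(sprintf("%s\t%s %d %d\t%s", pd$entities$id,
                           pd$entities$type, pd$entities$start,
                           pd$entities$end, pd$entities$text),
                   collapse = "\n"), "\n") else ""
    re <- read_standoff_document(pd$text, a1, write_standoff(pd),
                                 doc_id = pd$doc_id)
    expect_equal(score_corpus(list(pd), list(re), strict = TRUE)$overall$f1,
                 if (length(pd$events) > 0) 1 else 0)
  }
})
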