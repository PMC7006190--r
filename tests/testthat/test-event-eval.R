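mk_trig <- function(spans, types)
  data.frame(tok_start = vapply(spans, `[`, 0, 1),
             tok_end = vapply(spans, `[`, 0, 2), type = types)

test_that("candidate enumeration respects role min/max constraints", {
  sch <- toy_schema()
  trig <- mk_trig(list(c(3, 3)), "Regulation")
  rels <- data.frame(src = 1, role = c("Theme", "Cause"),
                     dst_kind = "entity", dst = 1:2,
                     filler_type = "Gene", support = c(1, 0.5))
  cands <- enumerate_candidate_events(trig, rels, sch)
  # mandatory Theme + optional Cause: {Theme}, {Theme, Cause}
  expect_length(cands, 2)
  sets <- lapply(cands, function(cd) sort(cd$args$role))
  expect_true(list(c("Cause", "Theme")) %in% sets || any(
    vapply(sets, identical, TRUE, y = c("Cause", "Theme"))))
  # zero relations with a mandatory Theme -> no candidates
  expect_length(enumerate_candidate_events(trig, rels[0, ], sch), 0)
  # relations with inadmissible roles are ignored
  rels_bad <- data.frame(src = 1, role = "Cause", dst_kind = "entity",
                         dst = 1, filler_type = "Gene", support = 1)
  expect_length(enumerate_candidate_events(trig, rels_bad, sch), 0)
})

test_that("candidate counts match brute-force subset enumeration", {
  # schema with one mandatory Theme and unbounded optional Site roles
  sch <- event_schema(
    entity_types = "Gene",
    event_types = list(Binding = list(
      Theme = list(fillers = "Gene", min = 1, max = 1),
      Site = list(fillers = "Gene", min = 0, max = 10))))
  trig <- mk_trig(list(c(1, 1)), "Binding")
  for (m_opt in 0:4) {
    rels <- data.frame(src = 1, role = c("Theme", rep("Site", m_opt)),
                       dst_kind = "entity", dst = seq_len(1 + m_opt),
                       filler_type = "Gene",
                       support = seq_len(1 + m_opt))
    cands <- enumerate_candidate_events(trig, rels, sch)
    expect_length(cands, 2^m_opt)   # Theme fixed, Sites free
  }
})

test_that("six-candidate configuration arises from two triggers and six relations", {
  # two triggers over shared arguments, mirroring the worked selection
  # example: each trigger's admissible relation subsets yield 6 candidates
  sch <- event_schema(
    entity_types = "Gene",
    event_types = list(
      Expression = list(Theme = list(fillers = "Gene", min = 1, max = 1)),
      Regulation = list(
        Theme = list(fillers = c("Gene", "Expression"), min = 1, max = 1),
        Cause = list(fillers = c("Gene", "Expression"), min = 0, max = 1))))
  trig <- mk_trig(list(c(2, 2), c(4, 4)), c("Expression", "Regulation"))
  rels <- rbind(
    data.frame(src = 1, role = "Theme", dst_kind = "entity", dst = 1,
               filler_type = "Gene", support = 2),
    data.frame(src = 2, role = "Theme", dst_kind = "entity", dst = 2,
               filler_type = "Gene", support = 1.5),
    data.frame(src = 2, role = "Theme", dst_kind = "trigger", dst = 1,
               filler_type = "Expression", support = 1.2),
    data.frame(src = 2, role = "Cause", dst_kind = "entity", dst = 3,
               filler_type = "Gene", support = 1),
    data.frame(src = 2, role = "Cause", dst_kind = "trigger", dst = 1,
               filler_type = "Expression", support = 0.8),
    data.frame(src = 2, role = "Theme", dst_kind = "entity", dst = 1,
               filler_type = "Gene", support = 0.5))
  cands <- enumerate_candidate_events(trig, rels, sch)
  # trigger 1: {Theme}; trigger 2: 3 Theme choices x (no Cause, 2 Causes),
  # capped by max = 1 per role -> 1 + 3 * 3 = 10; six relations feed them
  expect_equal(length(cands), 10)
  expect_equal(nrow(rels), 6)
  # every candidate satisfies the schema (independent validator)
  for (cd in cands)
    expect_true(bioevex:::schema_counts_ok(sch, trig$type[cd$trigger],
                                           cd$args$role))
})

test_that("role-label sequences follow the assignment and precedence rules", {
  trig <- mk_trig(list(c(3, 3), c(1, 1)), c("Regulation", "Expression"))
  ents <- mk_trig(list(c(5, 6)), "Gene")
  cand <- list(trigger = 1,
               args = data.frame(role = "Theme", dst_kind = "entity", dst = 1))
  expect_equal(role_label_sequence(cand, 6, trig, ents),
               c("none", "none", "event_trigger", "none", "Theme", "Theme"))
  # no arguments: only trigger tokens non-none
  cand0 <- list(trigger = 1, args = data.frame(role = character(0),
                                               dst_kind = character(0),
                                               dst = integer(0)))
  expect_equal(role_label_sequence(cand0, 4, trig, ents),
               c("none", "none", "event_trigger", "none"))
  # nested Cause filler: the sub-event's trigger tokens carry the role
  cand_n <- list(trigger = 1,
                 args = data.frame(role = "Cause", dst_kind = "trigger",
                                   dst = 2))
  expect_equal(role_label_sequence(cand_n, 4, trig, ents)[1], "Cause")
  # trigger beats argument role on overlap
  cand_ov <- list(trigger = 1,
                  args = data.frame(role = "Theme", dst_kind = "trigger",
                                    dst = 1))
  expect_equal(role_label_sequence(cand_ov, 4, trig, ents)[3],
               "event_trigger")
})

test_that("event scoring is a proper log-softmax pair with s_e = p1 - p2", {
  docs <- generate_corpus(3, cfg = synthetic_config(seed = 12))
  m <- raw_model(docs, hidden = 5, ee_hidden = 4)
  toks <- c("We", "observed", "expression", "of", "grk1", ".")
  enc <- encode_sentence(m, toks, c("O", "O", "O", "O", "Gene", "O"))
  trig <- recognize_triggers(m, enc, threshold_t = -Inf)
  rl <- c("none", "none", "event_trigger", "none", "Theme", "none")
  ev <- evaluate_event(m, enc, trig, rl)
  expect_equal(sum(exp(ev$p_e)), 1, tolerance = 1e-9)
  expect_equal(sum(exp(ev$p_m)), 1, tolerance = 1e-9)
  expect_equal(ev$s_e, ev$p_e[1] - ev$p_e[2])
  # symmetric probabilities give zero support
  expect_equal(log(0.5) - log(0.5), 0)
  # degenerate closed form: zero EE recurrence leaves only the biases, so
  # s_e is exactly the log-softmax margin of b_val
  m0 <- m
  for (nm in c("ee_f", "ee_b"))
    for (p in names(m0$params[[nm]])) m0$params[[nm]][[p]][] <- 0
  m0$params$W_val[] <- 0
  m0$params$b_val <- c(0.7, -0.4)
  ev0 <- evaluate_event(m0, enc, trig, rl)
  expect_equal(ev0$s_e, 0.7 - (-0.4), tolerance = 1e-12)
  # deterministic at prediction
  expect_identical(evaluate_event(m, enc, trig, rl)$p_e, ev$p_e)
})

test_that("undersampling balances negatives and is seed-deterministic", {
  pos <- c(rep(TRUE, 3), rep(FALSE, 10))
  kept <- undersample_negatives(pos, seed = 4)
  expect_equal(sum(pos[kept]), 3)
  expect_equal(sum(!pos[kept]), 3)
  expect_identical(kept, undersample_negatives(pos, seed = 4))
  # no positives: exactly one negative kept
  expect_length(undersample_negatives(rep(FALSE, 5), seed = 1), 1)
  expect_length(undersample_negatives(logical(0), seed = 1), 0)
})
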