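# Worked two-candidate instance: one event (s_e = 3.0) covering a trigger
# (s_t = 1.2) and a relation (s_r = 0.8), with a leftover trigger (0.5)
# and relation (0.4).
worked_bundle <- function() {
  support_bundle(trigger_support = c(1.2, 0.5),
                 relation_support = c(0.8, 0.4),
                 cand_support = 3.0,
                 cand_trigger = 1L,
                 cand_rels = list(1L))
}

test_that("penalty arithmetic reproduces the hand-computed instances", {
  b <- worked_bundle()
  # max(1 - 0.5*3, 0) + 0.25*0.5 + 0.125*0.4 = 0 + 0.125 + 0.05
  expect_equal(penalty_score(1L, b), 0.175, tolerance = 1e-12)
  # empty selection wastes everything positive
  expect_equal(penalty_score(integer(0), b),
               0.25 * (1.2 + 0.5) + 0.125 * (0.8 + 0.4), tolerance = 1e-12)
  expect_equal(penalty_score(integer(0), b), 0.575, tolerance = 1e-12)
  # empty candidate set, nothing positive left over -> zero penalty
  b0 <- support_bundle(numeric(0), numeric(0), numeric(0), integer(0),
                       list())
  expect_equal(penalty_score(integer(0), b0), 0)
  # negative supports contribute no waste
  bneg <- support_bundle(c(-3), c(-1), numeric(0), integer(0), list())
  expect_equal(penalty_score(integer(0), bneg), 0)
  # unknown candidate index errors
  expect_error(penalty_score(5L, b), "not present")
})

test_that("brute-force selection is exact on the worked instances", {
  b <- worked_bundle()
  r <- select_events_bruteforce(b)
  expect_equal(r$chosen, 1L)   # 0.175 < 0.575: choosing the event wins
  expect_equal(r$penalty, 0.175, tolerance = 1e-12)
  # empty C: waste-only penalty
  b0 <- support_bundle(c(0.6), c(0.2), numeric(0), integer(0), list())
  r0 <- select_events_bruteforce(b0)
  expect_equal(r0$chosen, integer(0))
  expect_equal(r0$penalty, 0.25 * 0.6 + 0.125 * 0.2)
  # strongly negative events with no waste to save: empty set optimal
  bneg <- support_bundle(c(-1), c(-2), c(-5, -4), c(1L, 1L),
                         list(1L, 1L))
  expect_equal(select_events_bruteforce(bneg)$chosen, integer(0))
  expect_error(select_events_bruteforce(random_bundle(21, 1)), "refuses")
})

test_that("greedy selection solves the worked instance and strict-benefit cases", {
  b <- worked_bundle()
  g <- select_events_greedy(b)
  expect_equal(g$chosen, 1L)
  expect_equal(g$penalty, 0.175, tolerance = 1e-12)
  # single candidate with s_e > 1/alpha: penalty term 0, always chosen
  b1 <- support_bundle(c(0), c(0), c(2.5), 1L, list(integer(0)))
  expect_equal(select_events_greedy(b1)$chosen, 1L)
})

test_that("greedy never beats the oracle; reported penalty re-evaluates exactly", {
  agree <- 0
  for (s in 1:300) {
    b <- random_bundle(sample(0:8, 1), seed = 2000 + s)
    bf <- select_events_bruteforce(b)
    gr <- select_events_greedy(b)
    expect_gte(gr$penalty + 1e-12, bf$penalty)
    expect_equal(gr$penalty, penalty_score(gr$chosen, b), tolerance = 1e-12)
    expect_equal(bf$penalty, penalty_score(bf$chosen, b), tolerance = 1e-12)
    if (abs(gr$penalty - bf$penalty) < 1e-9) agree <- agree + 1
  }
  expect_gt(agree / 300, 0.9)  # greedy finds the optimum almost always
})

test_that("enlarging the candidate set never increases the oracle's optimum", {
  for (s in 1:50) {
    b_full <- random_bundle(8, seed = 3000 + s)
    pen_prev <- Inf
    for (k in 0:8) {
      b_k <- support_bundle(b_full$trigger_support, b_full$relation_support,
                            b_full$cand_support[seq_len(k)],
                            b_full$cand_trigger[seq_len(k)],
                            b_full$cand_rels[seq_len(k)])
      pen_k <- select_events_bruteforce(b_k)$penalty
      expect_lte(pen_k, pen_prev + 1e-12)
      pen_prev <- pen_k
    }
  }
})

test_that("topological ordering puts nested children first and breaks cycles", {
  # candidate 1 (trigger A) takes trigger B as Cause; candidate 2 on B
  b <- support_bundle(
    trigger_support = c(1, 1), relation_support = c(0.5, 0.7),
    cand_support = c(1, 1), cand_trigger = c(1L, 2L),
    cand_rels = list(1L, 2L),
    cand_filler_triggers = list(2L, integer(0)))
  ord <- topological_sort_candidates(b)
  expect_equal(ord, c(2L, 1L))   # B's candidate precedes A's
  # no nesting: stable input order
  b_flat <- random_bundle(5, seed = 77)
  expect_equal(topological_sort_candidates(b_flat), 1:5)
  # mutual nesting: lower-support edge dropped, order still defined
  b_cyc <- support_bundle(
    trigger_support = c(1, 1), relation_support = c(0.9, 0.1),
    cand_support = c(1, 1), cand_trigger = c(1L, 2L),
    cand_rels = list(1L, 2L),
    cand_filler_triggers = list(2L, 1L))
  expect_warning(ord2 <- topological_sort_candidates(b_cyc), "cyclic")
  expect_setequal(ord2, 1:2)
  expect_equal(ord2[1], 2L)  # the high-support edge 1->2 survives
})

test_that("loop detector drops exactly the cycle-closing events", {
  mk_ev <- function(id, subs) list(
    id = id, trigger_id = "T1",
    args = if (length(subs)) data.frame(role = "Cause", filler_id = subs,
                                        filler_kind = "event")
           else data.frame(role = character(0), filler_id = character(0),
                           filler_kind = character(0)))
  # mutual pair in order: the second is dropped
  kept <- detect_and_discard_loops(list(mk_ev("E1", "E2"), mk_ev("E2", "E1")))
  expect_equal(vapply(kept, `[[`, "", "id"), "E1")
  # chain E1 -> E2 -> E3 all kept
  kept2 <- detect_and_discard_loops(list(mk_ev("E3", character(0)),
                                         mk_ev("E2", "E3"), mk_ev("E1", "E2")))
  expect_length(kept2, 3)
  # self reference dropped
  expect_length(detect_and_discard_loops(list(mk_ev("E1", "E1"))), 0)
})

test_that("loop detector output is acyclic on random cyclic event soups", {
  set.seed(99)
  for (rep_i in 1:200) {
    n <- sample(2:7, 1)
    ids <- sprintf("E%d", 1:n)
    evs <- lapply(1:n, function(i) {
      subs <- sample(ids, sample(0:2, 1))
      list(id = ids[i], trigger_id = "T1",
           args = if (length(subs)) data.frame(role = "Cause",
                                               filler_id = subs,
                                               filler_kind = "event")
                  else data.frame(role = character(0),
                                  filler_id = character(0),
                                  filler_kind = character(0)))
    })
    kept <- detect_and_discard_loops(evs)
    kept_named <- setNames(kept, vapply(kept, `[[`, "", "id"))
    expect_length(bioevex:::event_graph_cycle(kept_named), 0)
    # dropped events each closed a cycle at insertion time: every kept
    # prefix is acyclic and re-running the detector keeps everything
    expect_length(detect_and_discard_loops(kept), length(kept))
  }
})

test_that("modification assignment takes the argmax with ties to None", {
  evs <- list(list(id = "E1", args = data.frame()),
              list(id = "E2", args = data.frame()),
              list(id = "E3", args = data.frame()))
  out <- assign_modifications(evs, list(log(c(0.7, 0.2, 0.1)),
                                        log(rep(1 / 3, 3)),
                                        log(c(0.1, 0.6, 0.3))))
  expect_equal(vapply(out, `[[`, "", "modification"),
               c("Negation", "None", "Speculation"))
  expect_length(assign_modifications(list(), list()), 0)
})
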