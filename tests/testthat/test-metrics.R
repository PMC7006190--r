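test_that("approximate span matching allows a one-token extension", {
  doc <- nested_fixture_doc()
  tk <- doc$tokens
  # identical spans
  expect_true(approximate_span_match(c(24, 32), c(24, 32), tk))
  # prediction missing the gold span's final token still matches:
  # gold "of grk1" (16, 23), pred "of" (16, 18)
  expect_true(approximate_span_match(c(16, 23), c(16, 18), tk))
  # disjoint spans two tokens away do not match
  expect_false(approximate_span_match(c(0, 15), c(24, 32), tk))
  # strict mode requires identity
  expect_false(approximate_span_match(c(16, 23), c(16, 18), tk,
                                      strict = TRUE))
  # strict matching never yields more matches than approximate
  set.seed(5)
  for (i in 1:50) {
    g <- sort(sample(0:47, 2)); p <- sort(sample(0:47, 2))
    expect_true(!approximate_span_match(g, p, tk, strict = TRUE) ||
                  approximate_span_match(g, p, tk))
  }
})

test_that("event matching is recursive over nested fillers", {
  doc <- nested_fixture_doc()
  # identical structures match
  expect_true(event_match(doc, doc, doc$events[["E2"]], doc$events[["E2"]]))
  # dropping the Cause argument breaks the match (role multiset)
  e2_slim <- doc$events[["E2"]]
  e2_slim$args <- e2_slim$args[1, , drop = FALSE]
  expect_false(event_match(doc, doc, doc$events[["E2"]], e2_slim))
  # a nested filler differing only in a sub-argument breaks the match
  doc_mut <- doc
  doc_mut$events[["E1"]]$args <-
    data.frame(role = "Theme", filler_id = "T2", filler_kind = "entity")
  expect_false(event_match(doc, doc_mut, doc$events[["E2"]],
                           doc_mut$events[["E2"]]))
})

test_that("corpus scoring counts greedy 1-1 matches", {
  docs <- generate_corpus(8, cfg = synthetic_config(seed = 21))
  # self-score is perfect for any generated corpus
  s <- score_corpus(docs, docs)
  expect_equal(s$overall$f1, 1)
  expect_equal(s$overall$recall, 1)
  expect_true(all(s$by_type$f1 == 1))

  # 2 gold events, 1 correct + 1 spurious prediction: P = R = F1 = 0.5
  doc <- NULL
  for (d in docs) if (length(d$events) >= 2) { doc <- d; break }
  expect_false(is.null(doc))
  pred <- doc
  keep <- names(doc$events)[1]
  # keep one correct event; fabricate a spurious one on a shifted span
  spur_trig <- doc$triggers[1, ]
  ev1 <- doc$events[[keep]]
  if (any(ev1$args$filler_kind == "event"))
    keep <- names(doc$events)[which(vapply(doc$events, function(e)
      all(e$args$filler_kind == "entity"), TRUE))[1]]
  ev1 <- doc$events[[keep]]
  far_tok <- doc$tokens[nrow(doc$tokens) - 1, ]
  pred$triggers <- rbind(doc$triggers,
                         data.frame(id = "T99", type = doc$triggers$type[1],
                                    start = far_tok$start, end = far_tok$end,
                                    text = far_tok$text,
                                    tok_start = 0, tok_end = 0, sentence = 0))
  spur <- ev1; spur$id <- "E99"; spur$trigger_id <- "T99"
  pred$events <- setNames(list(ev1, spur), c(keep, "E99"))
  ngold <- length(doc$events)
  s2 <- score_corpus(list(doc), list(pred))
  expect_equal(s2$overall$tp, 1)
  expect_equal(s2$overall$precision, 0.5)
  expect_equal(s2$overall$recall, 1 / ngold)

  # zero predictions: P -> 0 by convention, R = 0
  empty <- doc; empty$events <- list(); empty$triggers <- doc$triggers[0, ]
  s3 <- score_corpus(list(doc), list(empty))
  expect_equal(s3$overall$precision, 0)
  expect_equal(s3$overall$recall, 0)
  expect_equal(s3$overall$f1, 0)

  expect_error(score_corpus(docs[1:2], docs[3:4]), "misaligned")
})

test_that("error typology assigns each errored event to one category", {
  f <- nested_fixture_texts()
  gold <- nested_fixture_doc()
  # wrong label: correct span, wrong event type
  a2_label <- sub("Gene_expression 0 15", "Positive_regulation 0 15",
                  sub("Gene_expression:T3", "Positive_regulation:T3", f$a2))
  a2_label <- sub("Cause:E1", "Theme:E1", a2_label)  # keep schema shape
  pred_label <- read_standoff_document(f$txt, f$a1, paste0(
    "T3\tPositive_regulation 0 15\tOver-expression\n",
    "E1\tPositive_regulation:T3 Theme:T2\n"), doc_id = "fig1")
  eb <- classify_errors(list(gold), list(pred_label))
  expect_equal(eb$count[eb$category == "wrong_trigger_label"], 1)

  # spurious trigger with no gold overlap -> wrong span
  pred_spur <- read_standoff_document(f$txt, f$a1, paste0(
    "T3\tGene_expression 19 23\tgrk1\n",
    "E1\tGene_expression:T3 Theme:T1\n"), doc_id = "fig1")
  eb2 <- classify_errors(list(gold), list(pred_spur))
  expect_gte(eb2$count[eb2$category == "wrong_trigger_span"], 1)

  # extra argument beyond a full gold match -> redundant arguments
  pred_red <- read_standoff_document(f$txt, f$a1, paste0(
    "T3\tGene_expression 0 15\tOver-expression\n",
    "T4\tPositive_regulation 24 32\tpromotes\n",
    "E1\tGene_expression:T3 Theme:T1\n",
    "E2\tPositive_regulation:T4 Theme:T2 Cause:E1\n",
    "E3\tPositive_regulation:T4 Theme:T2\n"), doc_id = "fig1")
  # E3 duplicates E2 minus Cause: E2 matches gold, E3 is unmatched and is
  # a subset (wrong args), while a superset prediction is redundant
  eb3 <- classify_errors(list(gold), list(pred_red))
  expect_equal(sum(eb3$count), 1)

  # categories partition: perfect prediction has zero errors
  eb0 <- classify_errors(list(gold), list(gold))
  expect_equal(sum(eb0$count), 0)
})
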