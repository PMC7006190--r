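# Shared fixtures: a hand-written nested-event document, tiny corpora and
# a cached small trained model (built once per test run).

# "over-expression of grk1 promotes tumorigenesis." with a Gene entity, a
# Carcinoma-like entity, a flat Expression event on "over-expression" and
# a Regulation event on "promotes" taking the Expression event as Cause —
# the canonical nested motif.
nested_fixture_schema <- function() {
  event_schema(
    entity_types = c("Gene", "Cancer"),
    event_types = list(
      Gene_expression = list(
        Theme = list(fillers = "Gene", min = 1, max = 1)),
      Positive_regulation = list(
        Theme = list(fillers = c("Cancer", "Gene_expression"), min = 1, max = 1),
        Cause = list(fillers = c("Gene", "Gene_expression"), min = 0, max = 1))))
}

nested_fixture_texts <- function() {
  txt <- "Over-expression of grk1 promotes tumorigenesis."
  a1 <- "T1\tGene 19 23\tgrk1\nT2\tCancer 33 46\ttumorigenesis\n"
  a2 <- paste0(
    "T3\tGene_expression 0 15\tOver-expression\n",
    "T4\tPositive_regulation 24 32\tpromotes\n",
    "E1\tGene_expression:T3 Theme:T1\n",
    "E2\tPositive_regulation:T4 Theme:T2 Cause:E1\n",
    "M1\tNegation E2\n")
  list(txt = txt, a1 = a1, a2 = a2)
}

nested_fixture_doc <- function() {
  f <- nested_fixture_texts()
  read_standoff_document(f$txt, f$a1, f$a2, doc_id = "fig1")
}

# a deliberately small trained model shared across test files
.toy_cache <- new.env(parent = emptyenv())

toy_model <- function() {
  if (is.null(.toy_cache$model)) {
    docs <- generate_corpus(10, cfg = synthetic_config(seed = 11))
    ctl <- evex_control(hidden = 16, char_channels = 8, tr_hidden = 32,
                        rc_hidden = 32, ee_hidden = 16, epochs = 60,
                        seed = 5)
    .toy_cache$docs <- docs
    .toy_cache$model <- evex_fit(docs, toy_schema(), ctl)
  }
  list(model = .toy_cache$model, docs = .toy_cache$docs)
}

# random-initialised (untrained) model around a given corpus
raw_model <- function(docs, schema = toy_schema(), seed = 1, ...) {
  ctl <- evex_control(..., seed = seed)
  vocab <- bioevex:::build_vocab(docs, schema)
  set.seed(seed)
  P <- bioevex:::init_params(vocab, ctl)
  structure(list(params = P, members = list(P), vocab = vocab,
                 schema = schema, control = ctl),
            class = "evex_model")
}

random_bundle <- function(n_cand, seed) {
  set.seed(seed)
  nt <- sample(1:3, 1); nr <- sample(1:5, 1)
  support_bundle(
    trigger_support = stats::rnorm(nt, 0, 2),
    relation_support = stats::rnorm(nr, 0, 2),
    cand_support = stats::rnorm(n_cand, 0, 2),
    cand_trigger = sample(nt, n_cand, replace = TRUE),
    cand_rels = lapply(seq_len(n_cand), function(i)
      sort(sample(nr, sample(0:min(3, nr), 1)))))
}
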