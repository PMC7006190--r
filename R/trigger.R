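# Trigger recognition surface: greedy left-to-right BILOU labelling with
# previous-label feedback, margin thresholding, support values and the
# scheduled-sampling schedule.

#' Scheduled-sampling probability (inverse sigmoid decay)
#'
#' Probability of feeding the gold previous trigger label (rather than the
#' model's own prediction) at a given training epoch:
#' `eps = k / (k + exp(epoch / k))`.
#'
#' @param epoch training epoch (0-based).
#' @param k decay constant, must be positive.
#' @return eps in (0, 1].
#' @export
scheduled_sampling_prob <- function(epoch, k = 10) {
  if (k <= 0) stop("config error: scheduled-sampling k must be > 0")
  stopifnot(epoch >= 0)
  k / (k + exp(epoch / k))
}

#' Encode a sentence with a fitted model's shared encoder
#'
#' Runs the character CNN and the entity-aware BiLSTM over one tokenized
#' sentence (dropout disabled).
#'
#' @param model an `evex_model`.
#' @param tokens character vector of token texts.
#' @param entity_labels character vector of per-token entity labels ("O"
#'   for non-entity tokens); must be enumerated by the schema.
#' @return list with `H` (n x 2*hidden BiLSTM states) and `E` (n x
#'   entity_dim entity-label embeddings), plus internal caches.
#' @export
encode_sentence <- function(model, tokens, entity_labels = NULL) {
  vocab <- model$vocab; ctl <- model$control
  if (is.null(entity_labels)) entity_labels <- rep("O", length(tokens))
  ent_ids <- match(entity_labels, vocab$entity_labels)
  if (anyNA(ent_ids))
    stop(sprintf("unknown entity label '%s' (schema must enumerate labels)",
                 entity_labels[which(is.na(ent_ids))[1]]), call. = FALSE)
  enc <- encoder_forward(model$params, ctl, vocab, tokens,
                         lapply(tokens, char_ids, vocab = vocab),
                         word_id(vocab, tokens), ent_ids, train = FALSE)
  enc
}

#' Character-CNN representation of a single word
#'
#' Convolution over character embeddings followed by channel-wise max
#' pooling; words shorter than the kernel are right-padded. Characters
#' outside the vocabulary map to the UNK character.
#'
#' @param model an `evex_model`.
#' @param word a single word.
#' @return numeric vector of length `char_channels`.
#' @export
char_encode <- function(model, word) {
  stopifnot(nchar(word) >= 1)
  charcnn_forward(char_ids(model$vocab, word), model$params$C_char,
                  model$params$W1, model$params$b1,
                  model$control$char_kernel, pad_id = 2L)$ch
}

#' Recognize event triggers in an encoded sentence
#'
#' Greedy left-to-right labelling: at each position the head scores
#' `[h_i, t_{i-1}]` (previous assigned-label embedding, learned start
#' vector at position 1); the best non-none label is assigned when its
#' log-probability margin over the none class exceeds `threshold_t`,
#' otherwise "O". Decoded spans carry a support value: the mean of their
#' tokens' margins.
#'
#' @param model an `evex_model`.
#' @param enc a sentence encoding from [encode_sentence()].
#' @param threshold_t margin threshold (default from the model's control).
#' @return list with `labels` (BILOU strings), `logp` (n x n_labels
#'   log-softmax matrix), `T` (assigned-label embeddings), `margins`, and
#'   `triggers` (data.frame tok_start/tok_end/type/support).
#' @export
recognize_triggers <- function(model, enc,
                               threshold_t = model$control$threshold_t) {
  trf <- tr_forward(model$params, model$control, model$vocab, enc$H,
                    mode = "predict", threshold = threshold_t)
  trigger_prediction(trf, model$vocab)
}

# shared assembly of a TriggerPrediction from a tr-forward result
trigger_prediction <- function(trf, vocab) {
  labels <- vocab$bilou[trf$fed]
  tr <- decode_bilou(labels)
  support <- vapply(seq_len(nrow(tr)), function(j)
    mean(trf$margins[tr$tok_start[j]:tr$tok_end[j]]), 0)
  tr$support <- if (nrow(tr)) support else numeric(0)
  list(labels = labels, logp = trf$LP, T = trf$T, margins = trf$margins,
       fed = trf$fed, triggers = tr)
}
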