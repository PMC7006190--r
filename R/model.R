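#' Control parameters for the joint extraction model
#'
#' Collects architecture sizes, training hyper-parameters and the
#' post-processing weights in one list. Defaults follow the published
#' configuration where one is stated (learning rate 0.007, positive:
#' negative class weight 5:1, weight decay 2e-4, batch size 16, thresholds
#' -2.0, scheduled-sampling k = 10, penalty weights 0.5/0.25/0.125,
#' leaky-relu activations, Adam, Xavier initialisation, LSTM dropout,
#' event undersampling); layer sizes are package defaults.
#'
#' @param word_dim,entity_dim,char_dim,char_kernel,char_channels encoder
#'   embedding sizes and character-CNN geometry.
#' @param hidden BiLSTM hidden size per direction.
#' @param encoder_layers number of stacked BiLSTM encoder layers.
#' @param trig_emb,role_emb trigger-label / role-label embedding sizes.
#' @param dist_dim,dist_clip distance-embedding size and clip value
#'   (token distances are clipped to `[0, dist_clip]`).
#' @param mid_kernel,mid_channels convolution geometry for the
#'   between-segment feature of the relation classifier.
#' @param tr_hidden,rc_hidden hidden sizes of the trigger/relation heads.
#' @param ee_hidden hidden size of the event-evaluation BiLSTM.
#' @param dropout dropout rate on encoder LSTM outputs (training only).
#' @param lr,weight_decay,batch_size,epochs Adam optimiser settings.
#' @param class_weight positive-class weight for trigger and relation
#'   losses (negative class has weight 1).
#' @param threshold_t,threshold_r margin thresholds for emitting triggers
#'   and relations.
#' @param ss_k scheduled-sampling decay constant k.
#' @param alpha,beta,gamma combination-strategy penalty weights.
#' @param candidate_cap maximum candidate events enumerated per trigger.
#' @param ensemble_size number of ensemble members to train.
#' @param mode event-assembly mode: `"cs"` (combination strategy),
#'   `"rule-single"`, `"rule-all"`, `"ee-probability"` or
#'   `"zero-threshold"`.
#' @param seed integer seed fixing initialisation, dropout, scheduled
#'   sampling and undersampling.
#' @return A named list of class `evex_control`.
#' @export
evex_control <- function(word_dim = 32L, entity_dim = 8L, char_dim = 8L,
                         char_kernel = 3L, char_channels = 16L,
                         hidden = 32L, encoder_layers = 1L,
                         trig_emb = 8L, role_emb = 8L,
                         dist_dim = 8L, dist_clip = 30L,
                         mid_kernel = 3L, mid_channels = 16L,
                         tr_hidden = 64L, rc_hidden = 64L, ee_hidden = 32L,
                         dropout = 0.5,
                         lr = 0.007, weight_decay = 2e-4,
                         batch_size = 16L, epochs = 100L,
                         class_weight = 5,
                         threshold_t = -2.0, threshold_r = -2.0,
                         ss_k = 10,
                         alpha = 0.5, beta = 0.25, gamma = 0.125,
                         candidate_cap = 128L,
                         ensemble_size = 1L,
                         mode = c("cs", "rule-single", "rule-all",
                                  "ee-probability", "zero-threshold"),
                         seed = 1L) {
  if (ss_k <= 0) stop("config error: scheduled-sampling k must be > 0")
  if (min(alpha, beta, gamma) < 0) stop("penalty weights must be >= 0")
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  structure(list(
    word_dim = word_dim, entity_dim = entity_dim, char_dim = char_dim,
    char_kernel = as.integer(char_kernel), char_channels = char_channels,
    hidden = hidden, encoder_layers = as.integer(encoder_layers),
    trig_emb = trig_emb, role_emb = role_emb,
    dist_dim = dist_dim, dist_clip = as.integer(dist_clip),
    mid_kernel = as.integer(mid_kernel), mid_channels = mid_channels,
    tr_hidden = tr_hidden, rc_hidden = rc_hidden, ee_hidden = ee_hidden,
    dropout = dropout, lr = lr, weight_decay = weight_decay,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    class_weight = class_weight,
    threshold_t = threshold_t, threshold_r = threshold_r, ss_k = ss_k,
    alpha = alpha, beta = beta, gamma = gamma,
    candidate_cap = as.integer(candidate_cap),
    ensemble_size = as.integer(ensemble_size),
    mode = match.arg(mode), seed = as.integer(seed)),
    class = "evex_control")
}

# Label inventories and lookup tables derived from corpus + schema.
build_vocab <- function(docs, schema) {
  words <- sort(unique(unlist(lapply(docs, function(d) d$tokens$text))))
  chars <- sort(unique(unlist(strsplit(words, ""))))
  list(
    words = c("<UNK>", words),
    chars = c("<UNK>", "<PAD>", chars),
    entity_labels = c("O", schema$entity_types),
    bilou = bilou_labels(schema),
    relations = c("none", schema_roles(schema)),
    role_labels = c("none", "event_trigger", schema_roles(schema))
  )
}

word_id <- function(vocab, w) {
  i <- match(w, vocab$words); ifelse(is.na(i), 1L, i)
}
char_ids <- function(vocab, w) {
  i <- match(strsplit(w, "")[[1]], vocab$chars)
  i[is.na(i)] <- 1L
  i
}

# Per-token entity labels for one sentence (tokens covered by an entity
# mention carry its type; unknown entity types are a config error).
entity_label_ids <- function(doc, sentence_index, vocab) {
  tok_idx <- which(doc$tokens$sentence == sentence_index)
  lab <- rep(1L, length(tok_idx))  # "O"
  ent <- doc$entities[doc$entities$sentence == sentence_index, , drop = FALSE]
  off <- if (length(tok_idx)) min(tok_idx) - 1L else 0L
  for (i in seq_len(nrow(ent))) {
    id <- match(ent$type[i], vocab$entity_labels)
    if (is.na(id))
      stop(sprintf("unknown entity label '%s' (schema must enumerate labels)",
                   ent$type[i]), call. = FALSE)
    lab[(ent$tok_start[i]:ent$tok_end[i]) - off] <- id
  }
  lab
}

# All learnable parameters, Xavier-initialised; embeddings included.
init_params <- function(vocab, ctl) {
  hd <- ctl$hidden
  S <- 2 * hd + ctl$trig_emb + ctl$entity_dim   # [H,T,E] slice width
  rdim <- 2 * S + ctl$mid_channels + ctl$dist_dim + 1L
  n_bilou <- length(vocab$bilou)
  d_in <- ctl$word_dim + ctl$entity_dim + ctl$char_channels
  d_ee <- 2 * hd + ctl$entity_dim + ctl$trig_emb + ctl$role_emb
  lstm_par <- function(d, h) list(Wx = xavier_init(d, 4 * h),
                                  Wh = xavier_init(h, 4 * h),
                                  b = rep(0, 4 * h))
  P <- list(
    C_char = xavier_init(length(vocab$chars), ctl$char_dim),
    W1 = xavier_init(ctl$char_kernel * ctl$char_dim, ctl$char_channels),
    b1 = rep(0, ctl$char_channels),
    W_word = xavier_init(length(vocab$words), ctl$word_dim),
    W_ent = xavier_init(length(vocab$entity_labels), ctl$entity_dim),
    T_emb = xavier_init(n_bilou + 1L, ctl$trig_emb),  # last row = t0 start
    W2 = xavier_init(2 * hd + ctl$trig_emb, ctl$tr_hidden),
    b2 = rep(0, ctl$tr_hidden),
    W3 = xavier_init(ctl$tr_hidden, n_bilou),
    b3 = rep(0, n_bilou),
    mid_adj = stats::runif(ctl$mid_channels, -0.1, 0.1),
    W_mid = xavier_init(ctl$mid_kernel * S, ctl$mid_channels),
    b_mid = rep(0, ctl$mid_channels),
    D_emb = xavier_init(ctl$dist_clip + 1L, ctl$dist_dim),
    W4 = xavier_init(rdim, ctl$rc_hidden),
    b4 = rep(0, ctl$rc_hidden),
    W5 = xavier_init(ctl$rc_hidden, length(vocab$relations)),
    b5 = rep(0, length(vocab$relations)),
    R_emb = xavier_init(length(vocab$role_labels), ctl$role_emb),
    W_val = xavier_init(2 * ctl$ee_hidden, 2L),
    b_val = rep(0, 2),
    W_mod = xavier_init(2 * ctl$ee_hidden, 3L),
    b_mod = rep(0, 3)
  )
  for (l in seq_len(ctl$encoder_layers)) {
    d_l <- if (l == 1) d_in else 2 * hd
    P[[paste0("enc", l, "_f")]] <- lstm_par(d_l, hd)
    P[[paste0("enc", l, "_b")]] <- lstm_par(d_l, hd)
  }
  P$ee_f <- lstm_par(d_ee, ctl$ee_hidden)
  P$ee_b <- lstm_par(d_ee, ctl$ee_hidden)
  P
}

# zero gradient container matching a parameter list
zero_like <- function(P) {
  rapply(P, function(x) x * 0, how = "replace")
}

flatten_params <- function(P, prefix = "") {
  out <- list()
  for (nm in names(P)) {
    x <- P[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x)) out <- c(out, flatten_params(x, key))
    else out[[key]] <- x
  }
  out
}

set_flat <- function(P, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) acc[[k]], path[-length(path)], P,
                 accumulate = FALSE)
  if (length(path) == 1) P[[path]] <- value
  else P[[path[1]]][[path[2]]] <- value
  P
}

# Adam with decoupled-from-nothing classic L2 weight decay added to the
# gradient (embedding tables included).
adam_init <- function(P) list(m = zero_like(P), v = zero_like(P), t = 0L)

adam_step <- function(P, G, st, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- function(p, g, m, v) {
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(P, G, M, V) {
    for (nm in names(P)) {
      if (is.list(P[[nm]])) {
        r <- walk(P[[nm]], G[[nm]], M[[nm]], V[[nm]])
        P[[nm]] <- r$P; M[[nm]] <- r$M; V[[nm]] <- r$V
      } else {
        r <- upd(P[[nm]], G[[nm]], M[[nm]], V[[nm]])
        P[[nm]] <- r$p; M[[nm]] <- r$m; V[[nm]] <- r$v
      }
    }
    list(P = P, M = M, V = V)
  }
  r <- walk(P, G, st$m, st$v)
  list(P = r$P, state = list(m = r$M, v = r$V, t = st$t))
}

grad_add <- function(G, P_sub) {
  for (nm in names(P_sub)) {
    if (is.list(P_sub[[nm]])) G[[nm]] <- grad_add(G[[nm]], P_sub[[nm]])
    else G[[nm]] <- G[[nm]] + P_sub[[nm]]
  }
  G
}
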