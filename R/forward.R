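# Per-sentence forward and backward passes wiring the shared encoder into
# the trigger-recognition (TR), relation-classification (RC) and
# event-evaluation (EE) heads. Gradients accumulate into a mutable
# environment G holding one array per parameter (same shapes as the
# parameter list).

new_grad_env <- function(P) {
  G <- new.env(parent = emptyenv())
  G$P <- zero_like(P)
  G
}

# add a block of row-gradients into an embedding table, rows may repeat
accum_rows <- function(M, rows, block) {
  u <- rowsum(block, rows)
  ri <- as.integer(rownames(u))
  M[ri, ] <- M[ri, , drop = FALSE] + u
  M
}

# ---- encoder -----------------------------------------------------------

encoder_forward <- function(P, ctl, vocab, tok_texts, char_id_list, wids,
                            ent_ids, train = FALSE) {
  n <- length(tok_texts)
  CH <- matrix(0, n, ctl$char_channels)
  ch_caches <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- charcnn_forward(char_id_list[[i]], P$C_char, P$W1, P$b1,
                          ctl$char_kernel, pad_id = 2L)
    CH[i, ] <- cc$ch
    ch_caches[[i]] <- cc$cache
  }
  E <- P$W_ent[ent_ids, , drop = FALSE]
  V <- cbind(P$W_word[wids, , drop = FALSE], E, CH)
  X <- V
  layer_states <- vector("list", ctl$encoder_layers)
  for (l in seq_len(ctl$encoder_layers)) {
    st <- bilstm_forward(X, P[[paste0("enc", l, "_f")]],
                         P[[paste0("enc", l, "_b")]], ctl$hidden)
    layer_states[[l]] <- st
    X <- st$H
  }
  H_raw <- X
  drop_mask <- NULL
  if (train && ctl$dropout > 0) {
    keep <- 1 - ctl$dropout
    drop_mask <- matrix(stats::rbinom(length(H_raw), 1, keep) / keep,
                        nrow(H_raw), ncol(H_raw))
    H <- H_raw * drop_mask
  } else H <- H_raw
  list(H = H, E = E, n = n,
       cache = list(ch_caches = ch_caches, wids = wids, ent_ids = ent_ids,
                    layer_states = layer_states, drop_mask = drop_mask))
}

encoder_backward <- function(dH, enc, P, ctl, G) {
  cc <- enc$cache
  if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
  for (l in ctl$encoder_layers:1) {
    pf <- P[[paste0("enc", l, "_f")]]; pb <- P[[paste0("enc", l, "_b")]]
    bb <- bilstm_backward(dH, cc$layer_states[[l]], pf, pb, ctl$hidden)
    G$P[[paste0("enc", l, "_f")]] <-
      grad_add(G$P[[paste0("enc", l, "_f")]], bb$f)
    G$P[[paste0("enc", l, "_b")]] <-
      grad_add(G$P[[paste0("enc", l, "_b")]], bb$b)
    dH <- bb$dX
  }
  dV <- dH
  wd <- ctl$word_dim; ed <- ctl$entity_dim
  G$P$W_word <- accum_rows(G$P$W_word, cc$wids, dV[, 1:wd, drop = FALSE])
  G$P$W_ent <- accum_rows(G$P$W_ent, cc$ent_ids,
                          dV[, (wd + 1):(wd + ed), drop = FALSE])
  dCH <- dV[, (wd + ed + 1):ncol(dV), drop = FALSE]
  accum_char <- function(rows, block) {
    G$P$C_char <- accum_rows(G$P$C_char, rows, block)
  }
  for (i in seq_len(enc$n))
    charcnn_backward(dCH[i, ], cc$ch_caches[[i]], P$W1, G, accum_char)
  invisible(NULL)
}

# ---- trigger recognition ----------------------------------------------

tr_forward <- function(P, ctl, vocab, H, mode = c("predict", "train"),
                       gold_ids = NULL, eps = 0,
                       threshold = ctl$threshold_t) {
  mode <- match.arg(mode)
  n <- nrow(H)
  nlab <- length(vocab$bilou)
  t0 <- nlab + 1L
  LP <- matrix(0, n, nlab)
  fed <- integer(n); prev <- integer(n); margins <- rep(NA_real_, n)
  caches <- vector("list", n)
  prev_id <- t0
  for (i in seq_len(n)) {
    x <- c(H[i, ], P$T_emb[prev_id, ])
    m2 <- mlp2_forward(x, P$W2, P$b2, P$W3, P$b3)
    lp <- log_softmax(m2$y)
    best <- which_max1(lp[-1]) + 1L
    margin <- lp[best] - lp[1]
    pred_id <- if (margin > threshold) best else 1L
    assigned <- if (mode == "train" && stats::runif(1) < eps)
      gold_ids[i] else pred_id
    LP[i, ] <- lp
    prev[i] <- prev_id
    fed[i] <- assigned
    margins[i] <- if (assigned != 1L) lp[assigned] - lp[1] else margin
    caches[[i]] <- m2
    prev_id <- assigned
  }
  list(LP = LP, fed = fed, prev = prev, margins = margins,
       T = P$T_emb[fed, , drop = FALSE], caches = caches)
}

tr_backward <- function(dLP, dT_rows, trf, P, ctl, G) {
  n <- nrow(dLP)
  hd2 <- 2 * ctl$hidden
  dH <- matrix(0, n, hd2)
  dTe <- matrix(0, n, ctl$trig_emb)  # grads wrt T_emb[prev[i],]
  for (i in seq_len(n)) {
    dy <- log_softmax_backward(dLP[i, ], trf$LP[i, ])
    mb <- mlp2_backward(dy, trf$caches[[i]], P$W2, P$W3)
    G$P$W2 <- G$P$W2 + mb$dW_in;  G$P$b2 <- G$P$b2 + mb$db_in
    G$P$W3 <- G$P$W3 + mb$dW_out; G$P$b3 <- G$P$b3 + mb$db_out
    dH[i, ] <- mb$dx[1:hd2]
    dTe[i, ] <- mb$dx[(hd2 + 1):length(mb$dx)]
  }
  G$P$T_emb <- accum_rows(G$P$T_emb, trf$prev, dTe)
  if (!is.null(dT_rows))
    G$P$T_emb <- accum_rows(G$P$T_emb, trf$fed, dT_rows)
  dH
}

# ---- relation classification ------------------------------------------

# pair geometry in local (sentence) 1-based inclusive token coordinates
pair_geometry <- function(s1, e1, s2, e2) {
  if (s1 <= s2) list(a = c(s1, e1), b = c(s2, e2), dir = 0)
  else list(a = c(s2, e2), b = c(s1, e1), dir = 1)
}

rc_forward_pair <- function(P, ctl, M, geo) {
  n <- nrow(M)
  src <- colmax_forward(M, geo$a[1]:geo$a[2])
  dst <- colmax_forward(M, geo$b[1]:geo$b[2])
  gap <- geo$b[1] - geo$a[2]          # start2 - end1
  mid_cache <- NULL
  if (gap > 1) {
    rows <- (geo$a[2] + 1):(geo$b[1] - 1)
    Mm <- M[rows, , drop = FALSE]
    npad <- max(0L, ctl$mid_kernel - nrow(Mm))
    if (npad > 0) Mm <- rbind(Mm, matrix(0, npad, ncol(Mm)))
    nwin <- nrow(Mm) - ctl$mid_kernel + 1L
    Wn <- do.call(cbind, lapply(seq_len(ctl$mid_kernel), function(o)
      Mm[(seq_len(nwin) - 1L) + o, , drop = FALSE]))
    A <- sweep(Wn %*% P$W_mid, 2, P$b_mid, "+")
    Y <- leaky_relu(A)
    amax <- apply(Y, 2, which.max)
    mid_v <- Y[cbind(amax, seq_len(ncol(Y)))]
    mid_cache <- list(rows = rows, Wn = Wn, A = A, amax = amax,
                      nreal = length(rows), nwin = nwin)
  } else mid_v <- P$mid_adj
  d <- min(max(gap, 0L), ctl$dist_clip)
  r <- c(src$v, mid_v, dst$v, P$D_emb[d + 1L, ], geo$dir)
  m2 <- mlp2_forward(r, P$W4, P$b4, P$W5, P$b5)
  lp <- log_softmax(m2$y)
  list(lp = lp, cache = list(src = src, dst = dst, mid = mid_cache,
                             d = d, m2 = m2, S = ncol(M)))
}

rc_backward_pair <- function(dlp, fwd, P, ctl, G, dM) {
  dy <- log_softmax_backward(dlp, fwd$lp)
  mb <- mlp2_backward(dy, fwd$cache$m2, P$W4, P$W5)
  G$P$W4 <- G$P$W4 + mb$dW_in;  G$P$b4 <- G$P$b4 + mb$db_in
  G$P$W5 <- G$P$W5 + mb$dW_out; G$P$b5 <- G$P$b5 + mb$db_out
  S <- fwd$cache$S; mc <- ctl$mid_channels
  dr <- mb$dx
  dsrc <- dr[1:S]
  dmid <- dr[(S + 1):(S + mc)]
  ddst <- dr[(S + mc + 1):(2 * S + mc)]
  dde <- dr[(2 * S + mc + 1):(2 * S + mc + ctl$dist_dim)]
  dM <- colmax_backward(dsrc, fwd$cache$src, dM)
  dM <- colmax_backward(ddst, fwd$cache$dst, dM)
  midc <- fwd$cache$mid
  if (is.null(midc)) {
    G$P$mid_adj <- G$P$mid_adj + dmid
  } else {
    dY <- matrix(0, nrow(midc$A), mc)
    dY[cbind(midc$amax, seq_len(mc))] <- dmid
    dA <- dY * leaky_relu_grad(midc$A)
    G$P$W_mid <- G$P$W_mid + t(midc$Wn) %*% dA
    G$P$b_mid <- G$P$b_mid + colSums(dA)
    dWn <- dA %*% t(P$W_mid)
    for (o in seq_len(ctl$mid_kernel)) {
      block <- dWn[, ((o - 1) * S + 1):(o * S), drop = FALSE]
      for (j in seq_len(midc$nwin)) {
        ridx <- j - 1L + o
        if (ridx <= midc$nreal)
          dM[midc$rows[ridx], ] <- dM[midc$rows[ridx], ] + block[j, ]
      }
    }
  }
  G$P$D_emb[fwd$cache$d + 1L, ] <- G$P$D_emb[fwd$cache$d + 1L, ] + dde
  dM
}

# ---- event evaluation --------------------------------------------------

ee_forward <- function(P, ctl, H, E, Tm, role_ids) {
  V <- P$R_emb[role_ids, , drop = FALSE]
  X <- cbind(H, E, Tm, V)
  st <- bilstm_forward(X, P$ee_f, P$ee_b, ctl$ee_hidden)
  n <- nrow(X)
  hlast <- c(st$fw$H[n, ], st$bw$H[n, ])
  yv <- as.vector(hlast %*% P$W_val) + P$b_val
  ym <- as.vector(hlast %*% P$W_mod) + P$b_mod
  pval <- log_softmax(yv)
  pmod <- log_softmax(ym)
  list(pval = pval, pmod = pmod, s_e = pval[1] - pval[2],
       cache = list(st = st, hlast = hlast, role_ids = role_ids, n = n))
}

# returns list(dH, dE_rows, dT_rows) as n x * matrices
ee_backward <- function(dpval, dpmod, fwd, P, ctl, G) {
  cc <- fwd$cache
  dyv <- log_softmax_backward(dpval, fwd$pval)
  dym <- log_softmax_backward(dpmod, fwd$pmod)
  G$P$W_val <- G$P$W_val + outer(cc$hlast, dyv)
  G$P$b_val <- G$P$b_val + dyv
  G$P$W_mod <- G$P$W_mod + outer(cc$hlast, dym)
  G$P$b_mod <- G$P$b_mod + dym
  dhlast <- as.vector(P$W_val %*% dyv) + as.vector(P$W_mod %*% dym)
  hd <- ctl$ee_hidden
  n <- cc$n
  dHe <- matrix(0, n, 2 * hd)
  dHe[n, 1:hd] <- dhlast[1:hd]
  dHe[1, (hd + 1):(2 * hd)] <- dhlast[(hd + 1):(2 * hd)]
  bb <- bilstm_backward(dHe, cc$st, P$ee_f, P$ee_b, hd)
  G$P$ee_f <- grad_add(G$P$ee_f, bb$f)
  G$P$ee_b <- grad_add(G$P$ee_b, bb$b)
  dX <- bb$dX
  hd2 <- 2 * ctl$hidden; ed <- ctl$entity_dim; td <- ctl$trig_emb
  G$P$R_emb <- accum_rows(G$P$R_emb, cc$role_ids,
                          dX[, (hd2 + ed + td + 1):ncol(dX), drop = FALSE])
  list(dH = dX[, 1:hd2, drop = FALSE],
       dE = dX[, (hd2 + 1):(hd2 + ed), drop = FALSE],
       dT = dX[, (hd2 + ed + 1):(hd2 + ed + td), drop = FALSE])
}
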