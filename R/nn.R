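# Neural primitives: LSTM (with BPTT), character CNN with adaptive max
# pooling, and dense-layer helpers. All hand-written in base R; analytic
# gradients are verified against numeric differentiation in the test
# suite.

# ---- LSTM --------------------------------------------------------------
# Gate layout along the 4*hd columns: input, forget, cell, output.

lstm_forward <- function(X, Wx, Wh, b, hd) {
  n <- nrow(X)
  XP <- X %*% Wx
  H <- matrix(0, n, hd); Cc <- matrix(0, n, hd)
  I <- matrix(0, n, hd); Fg <- matrix(0, n, hd)
  G <- matrix(0, n, hd); O <- matrix(0, n, hd); TC <- matrix(0, n, hd)
  h <- rep(0, hd); cprev <- rep(0, hd)
  for (t in seq_len(n)) {
    z <- XP[t, ] + as.vector(h %*% Wh) + b
    i <- sigmoid(z[1:hd])
    f <- sigmoid(z[(hd + 1):(2 * hd)])
    g <- tanh(z[(2 * hd + 1):(3 * hd)])
    o <- sigmoid(z[(3 * hd + 1):(4 * hd)])
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[t, ] <- i; Fg[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    Cc[t, ] <- cc; TC[t, ] <- tc; H[t, ] <- h
    cprev <- cc
  }
  list(H = H, cache = list(X = X, I = I, Fg = Fg, G = G, O = O, Cc = Cc,
                           TC = TC, H = H, hd = hd))
}

# dH: n x hd gradient wrt the hidden outputs. Returns dX and parameter
# gradients.
lstm_backward <- function(dH, cache, Wx, Wh) {
  X <- cache$X; hd <- cache$hd
  n <- nrow(X)
  I <- cache$I; Fg <- cache$Fg; G <- cache$G; O <- cache$O
  Cc <- cache$Cc; TC <- cache$TC; H <- cache$H
  dZ <- matrix(0, n, 4 * hd)
  dh_next <- rep(0, hd); dc_next <- rep(0, hd)
  for (t in n:1) {
    dh <- dH[t, ] + dh_next
    cprev <- if (t > 1) Cc[t - 1, ] else rep(0, hd)
    do_ <- dh * TC[t, ]
    dc <- dh * O[t, ] * (1 - TC[t, ]^2) + dc_next
    di <- dc * G[t, ]
    dg <- dc * I[t, ]
    df <- dc * cprev
    dc_next <- dc * Fg[t, ]
    dz <- c(di * I[t, ] * (1 - I[t, ]),
            df * Fg[t, ] * (1 - Fg[t, ]),
            dg * (1 - G[t, ]^2),
            do_ * O[t, ] * (1 - O[t, ]))
    dZ[t, ] <- dz
    dh_next <- as.vector(Wh %*% dz)
  }
  Hprev <- rbind(rep(0, hd), H[-n, , drop = FALSE])
  list(dX = dZ %*% t(Wx),
       dWx = t(X) %*% dZ,
       dWh = t(Hprev) %*% dZ,
       db = colSums(dZ))
}

# Bidirectional wrapper. Returns H = [forward | backward] (n x 2hd).
bilstm_forward <- function(X, pf, pb, hd) {
  fw <- lstm_forward(X, pf$Wx, pf$Wh, pf$b, hd)
  n <- nrow(X)
  rev_idx <- n:1
  bw <- lstm_forward(X[rev_idx, , drop = FALSE], pb$Wx, pb$Wh, pb$b, hd)
  list(H = cbind(fw$H, bw$H[rev_idx, , drop = FALSE]),
       fw = fw, bw = bw, rev_idx = rev_idx)
}

bilstm_backward <- function(dH, st, pf, pb, hd) {
  n <- nrow(dH)
  rev_idx <- st$rev_idx
  bf <- lstm_backward(dH[, 1:hd, drop = FALSE], st$fw$cache, pf$Wx, pf$Wh)
  bb <- lstm_backward(dH[rev_idx, (hd + 1):(2 * hd), drop = FALSE],
                      st$bw$cache, pb$Wx, pb$Wh)
  list(dX = bf$dX + bb$dX[rev_idx, , drop = FALSE],
       f = list(Wx = bf$dWx, Wh = bf$dWh, b = bf$db),
       b = list(Wx = bb$dWx, Wh = bb$dWh, b = bb$db))
}

# ---- character CNN -----------------------------------------------------
# Convolution over character embeddings followed by channel-wise adaptive
# max pooling; words shorter than the kernel are right-padded with the PAD
# character.

charcnn_forward <- function(char_ids, C_char, W1, b1, k, pad_id) {
  L <- length(char_ids)
  if (L < k) { char_ids <- c(char_ids, rep(pad_id, k - L)); L <- k }
  E <- C_char[char_ids, , drop = FALSE]
  nwin <- L - k + 1L
  Wn <- do.call(cbind, lapply(seq_len(k), function(o)
    E[(seq_len(nwin) - 1L) + o, , drop = FALSE]))
  A <- sweep(Wn %*% W1, 2, b1, "+")
  Y <- leaky_relu(A)
  amax <- apply(Y, 2, which.max)
  list(ch = Y[cbind(amax, seq_len(ncol(Y)))],
       cache = list(ids = char_ids, Wn = Wn, A = A, amax = amax, k = k))
}

# G is the gradient environment (fields under G$P); accum_char(rows,
# block) scatters row gradients into the character embedding table.
charcnn_backward <- function(dch, cache, W1, G, accum_char) {
  nc <- length(dch)
  Wn <- cache$Wn
  dY <- matrix(0, nrow(Wn), nc)
  dY[cbind(cache$amax, seq_len(nc))] <- dch
  dA <- dY * leaky_relu_grad(cache$A)
  G$P$W1 <- G$P$W1 + t(Wn) %*% dA
  G$P$b1 <- G$P$b1 + colSums(dA)
  dWn <- dA %*% t(W1)
  cd <- ncol(dWn) / cache$k
  nwin <- nrow(dWn)
  for (o in seq_len(cache$k)) {
    block <- dWn[, ((o - 1) * cd + 1):(o * cd), drop = FALSE]
    rows <- cache$ids[(seq_len(nwin) - 1L) + o]
    accum_char(rows, block)
  }
  invisible(NULL)
}

# ---- dense helpers -----------------------------------------------------

# two-layer scorer y = W_out(f(W_in x + b_in) + b_out) with leaky-relu,
# as used by the trigger and relation heads
mlp2_forward <- function(x, W_in, b_in, W_out, b_out) {
  a <- as.vector(x %*% W_in) + b_in
  hrel <- leaky_relu(a)
  y <- as.vector(hrel %*% W_out) + b_out
  list(y = y, a = a, hrel = hrel, x = x)
}

mlp2_backward <- function(dy, cache, W_in, W_out) {
  dW_out <- outer(cache$hrel, dy)
  db_out <- dy
  dhrel <- as.vector(W_out %*% dy)
  da <- dhrel * leaky_relu_grad(cache$a)
  dW_in <- outer(cache$x, da)
  db_in <- da
  dx <- as.vector(W_in %*% da)
  list(dx = dx, dW_in = dW_in, db_in = db_in, dW_out = dW_out,
       db_out = db_out)
}

# column-wise max over a row slice of M, with argmax cache
colmax_forward <- function(M, rows) {
  S <- M[rows, , drop = FALSE]
  amax <- apply(S, 2, which.max)
  list(v = S[cbind(amax, seq_len(ncol(S)))], rows = rows, amax = amax)
}

# returns an n x p sparse-ish gradient contribution added into dM
colmax_backward <- function(dv, cache, dM) {
  idx <- cbind(cache$rows[cache$amax], seq_along(dv))
  dM[idx] <- dM[idx] + dv
  dM
}
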