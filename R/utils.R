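# Small numeric helpers shared across the neural modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_softmax <- function(y) y - logsumexp(y)

# gradient of loss wrt pre-softmax scores, given grad wrt log-probs
log_softmax_backward <- function(dlp, lp) dlp - exp(lp) * sum(dlp)

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Xavier/Glorot uniform initialisation for a nr x nc weight matrix.
xavier_init <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic argmax with lowest-index tie-break
which_max1 <- function(x) which(x == max(x))[1L]
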