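# Low-level neural-network primitives. The LSTM recurrence and the softmax
# cross-entropy run in compiled code (src/lstm.cpp); everything here deals in
# time-major stacked matrices: row block t (of B rows) of an (M*B) x *
# matrix is timestep t for the whole minibatch. Gradients are hand-derived
# and verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# inputs: (M*B) x 4H precomputed input contributions (W_x x_t); bias is
# added at every step, extra (B x 4H, e.g. the code contribution W_z z) too
# when supplied. Returns hidden/cell states Hs, Cs ((M+1)*B x H, zero
# initial block first) and activation caches.
lstm_forward <- function(inputs, Wh, B, M, bias = NULL, extra = NULL) {
  if (is.null(bias)) bias <- numeric(ncol(inputs))
  if (is.null(extra)) extra <- matrix(0, 1, ncol(inputs))
  lstm_forward_cpp(inputs, Wh, bias, extra, B, M)
}

# dHs: (M*B) x H, block t = gradient arriving at the state produced at step
# t; dh_last: extra gradient at the final hidden state.
lstm_backward <- function(cache, Wh, dHs, dh_last) {
  lstm_backward_cpp(cache$Hs, cache$Cs, cache$Gates, cache$TC, Wh, dHs,
                    dh_last, nrow(dh_last), nrow(dHs) / nrow(dh_last))
}

# row block t (1-based) of a stacked matrix
block_rows <- function(m, t, B) m[((t - 1) * B + 1):(t * B), , drop = FALSE]

# Softmax cross-entropy. logits: n x A, target: integer vector (1-based).
# Returns per-row nll and the gradient of sum(w * nll) w.r.t. logits.
softmax_xent <- function(logits, target, w = 1) {
  if (length(w) == 1) w <- rep(w, nrow(logits))
  out <- softmax_xent_cpp(logits, as.integer(target), w)
  list(nll = as.vector(out$nll), dlogits = out$dlogits)
}

# Accumulate gradient rows of an embedding/lookup matrix: dW[idx[r], ] += dG[r, ].
index_add <- function(dW, idx, dG) {
  sums <- rowsum(dG, group = idx)
  rows <- as.integer(rownames(sums))
  dW[rows, ] <- dW[rows, , drop = FALSE] + sums
  dW
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim_or_len(p))),
       v = lapply(params, function(p) array(0, dim = dim_or_len(p))),
       t = 0)
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) {
  z <- p; z[] <- 0; z
})
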