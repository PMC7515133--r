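#' Training configuration for the neural estimator
#'
#' @param hidden LSTM hidden size of encoder and decoder trunks.
#' @param code_dim dimension k of the Gaussian code.
#' @param n_components mixture components per conditional of the code
#'   marginal flow.
#' @param batch_size minibatch size.
#' @param lr Adam step size.
#' @param max_epochs hard cap on training passes.
#' @param patience passes without validation improvement before stopping
#'   (1 = stop at the first non-improving pass).
#' @param clip gradient-norm clip.
#' @param sigma_floor additive floor on the encoder scale (strict
#'   positivity); set 0 to disable.
#' @param scale_param `"softplus"` (default, `sigma = softplus(W h) + floor`)
#'   or `"square"` (the literal `(W h)^2 + floor`).
#' @param init_scale multiplier on the `1/sqrt(hidden)` uniform init range.
#' @param lr_decay multiplicative decay of the Adam step per pass (1 = none).
#' @param pad_symbol optional alphabet index masked out of both prediction
#'   losses (for padded corpus windows).
#' @return A list of class `nprd_config`.
#' @export
nprd_config <- function(hidden = 32, code_dim = 8, n_components = 6,
                        batch_size = 64, lr = 1e-3, max_epochs = 50,
                        patience = 1, clip = 5, sigma_floor = 1e-4,
                        scale_param = c("softplus", "square"),
                        init_scale = 1, lr_decay = 1,
                        pad_symbol = NA_integer_) {
  structure(list(hidden = hidden, code_dim = code_dim,
                 n_components = n_components, batch_size = batch_size,
                 lr = lr, max_epochs = max_epochs, patience = patience,
                 clip = clip, sigma_floor = sigma_floor,
                 scale_param = match.arg(scale_param),
                 init_scale = init_scale, lr_decay = lr_decay,
                 pad_symbol = pad_symbol),
            class = "nprd_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

nprd_init_params <- function(A, cfg, seed) {
  H <- cfg$hidden; k <- cfg$code_dim; C <- cfg$n_components
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  u <- function(nr, nc, r = cfg$init_scale / sqrt(H))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  p <- list(
    Wxe = u(A, 4 * H), Whe = u(H, 4 * H), be = rep(0, 4 * H),
    Wmu = u(H, k), bmu = rep(0, k),
    Wsg = u(H, k),
    # softplus(0.5413) = 1: start with unit scales
    bsg = rep(if (cfg$scale_param == "softplus") 0.5413 else 1, k),
    Weta = u(H, A), beta_b = rep(0, A),
    Wxd = u(A + 1, 4 * H), Wzd = u(k, 4 * H), Whd = u(H, 4 * H),
    bd = rep(0, 4 * H),
    Wod = u(H, A, r = 0.01), bod = rep(0, A)
  )
  fl <- nprd_flow(k, C, init = "jitter", seed = seed + 1)
  for (nm in c("Fp", "Fpb", "Fm", "Fmb", "Fs", "Fsb")) p[[nm]] <- fl[[nm]]
  # forget-gate bias 1: standard LSTM trick for gradient flow early on
  p$be[(H + 1):(2 * H)] <- 1
  p$bd[(H + 1):(2 * H)] <- 1
  p
}

#' Extract the code-marginal flow from a fitted bundle
#' @param bundle an `nprd` object.
#' @return An [nprd_flow()].
#' @export
bundle_flow <- function(bundle) {
  cfg <- bundle$config
  fl <- list(k = cfg$code_dim, C = cfg$n_components,
             Fp = bundle$params$Fp, Fpb = bundle$params$Fpb,
             Fm = bundle$params$Fm, Fmb = bundle$params$Fmb,
             Fs = bundle$params$Fs, Fsb = bundle$params$Fsb)
  class(fl) <- "nprd_flow"
  fl
}

encoder_scale <- function(sraw, cfg) {
  if (cfg$scale_param == "softplus") softplus(sraw) + cfg$sigma_floor
  else sraw^2 + cfg$sigma_floor
}

# Full forward (and optionally backward) pass on one minibatch.
# X, Y: B x M integer matrices (past, future); eps: B x k noise.
# All per-timestep head computations are stacked into single (B*M)-row
# matrix operations; only the LSTM recurrence itself is a loop.
nprd_step <- function(params, cfg, X, Y, lambda, eps, A, grad = TRUE) {
  B <- nrow(X); M <- ncol(X); H <- cfg$hidden; k <- cfg$code_dim
  maskp <- matrix(1, B, M); maskf <- matrix(1, B, M)
  if (!is.na(cfg$pad_symbol)) {
    maskp[X == cfg$pad_symbol] <- 0
    maskf[Y == cfg$pad_symbol] <- 0
  }
  # ---- encoder ----
  enc_all <- params$Wxe[as.vector(X), , drop = FALSE]
  enc <- lstm_forward(enc_all, params$Whe, B, M, bias = params$be)
  hM <- block_rows(enc$Hs, M + 1L, B)
  mu <- hM %*% params$Wmu + rep(params$bmu, each = B)
  sraw <- hM %*% params$Wsg + rep(params$bsg, each = B)
  sigma <- encoder_scale(sraw, cfg)
  z <- mu + sigma * eps
  # past-marginal (eta) losses off the shared trunk: h_{t-1} predicts x_t
  Henc <- enc$Hs[seq_len(M * B), , drop = FALSE]    # h_0 .. h_{M-1}
  eta_logits <- Henc %*% params$Weta + rep(params$beta_b, each = B * M)
  eta_sx <- softmax_xent(eta_logits, as.vector(X), w = as.vector(maskp) / B)
  eta_nll <- rowSums(matrix(eta_sx$nll * as.vector(maskp), B, M))
  # ---- decoder ----
  inp_all <- c(rep(A + 1L, B), as.vector(Y[, -M, drop = FALSE]))
  zW <- z %*% params$Wzd
  dec_all <- params$Wxd[inp_all, , drop = FALSE]
  dec <- lstm_forward(dec_all, params$Whd, B, M, bias = params$bd, extra = zW)
  Hdec <- dec$Hs[-seq_len(B), , drop = FALSE]       # h_1 .. h_M
  dec_logits <- Hdec %*% params$Wod + rep(params$bod, each = B * M)
  dec_sx <- softmax_xent(dec_logits, as.vector(Y), w = as.vector(maskf) / B)
  fut_nll <- rowSums(matrix(dec_sx$nll * as.vector(maskf), B, M))
  # ---- rate terms ----
  lpg <- rowSums(-0.5 * log(2 * pi) - log(sigma) - 0.5 * eps^2)
  flow <- list(k = k, C = cfg$n_components, Fp = params$Fp, Fpb = params$Fpb,
               Fm = params$Fm, Fmb = params$Fmb, Fs = params$Fs,
               Fsb = params$Fsb)
  class(flow) <- "nprd_flow"
  fq <- flow_logq(flow, z, grad = grad, w = if (grad) -lambda / B else 1)
  obj_i <- fut_nll + lambda * (lpg - fq$logq) + eta_nll
  out <- list(objective = mean(obj_i), obj_i = obj_i, fut_nll = fut_nll,
              past_nll = eta_nll, lpg = lpg, logq = fq$logq,
              mu = mu, sigma = sigma, z = z)
  if (!grad) return(out)

  g <- zero_like(params)
  for (nm in names(fq$grads)) g[[nm]] <- fq$grads[[nm]]
  # ---- decoder backward ----
  dl_dec <- dec_sx$dlogits                          # (B*M) x A
  g$Wod <- crossprod(Hdec, dl_dec)
  g$bod <- colSums(dl_dec)
  dH_dec <- dl_dec %*% t(params$Wod)
  bd_dec <- lstm_backward(dec, params$Whd, dH_dec,
                          dh_last = matrix(0, B, H))
  g$Whd <- bd_dec$dWh
  dG_dec <- bd_dec$dInputs                          # (B*M) x 4H
  g$Wxd <- index_add(g$Wxd, inp_all, dG_dec)
  g$bd <- colSums(dG_dec)
  sumG <- matrix(0, B, 4 * H)
  for (t in seq_len(M)) sumG <- sumG + block_rows(dG_dec, t, B)
  dz <- fq$dz + sumG %*% t(params$Wzd)
  g$Wzd <- crossprod(z, sumG)
  # ---- code / scale backward ----
  dmu <- dz
  dsigma <- dz * eps - (lambda / B) / sigma
  dsraw <- if (cfg$scale_param == "softplus") dsigma * sigmoid(sraw)
           else dsigma * 2 * sraw
  g$Wmu <- crossprod(hM, dmu); g$bmu <- colSums(dmu)
  g$Wsg <- crossprod(hM, dsraw); g$bsg <- colSums(dsraw)
  dhM <- dmu %*% t(params$Wmu) + dsraw %*% t(params$Wsg)
  # ---- encoder backward (eta heads + code head) ----
  dl_eta <- eta_sx$dlogits
  g$Weta <- crossprod(Henc, dl_eta)
  g$beta_b <- colSums(dl_eta)
  dH_eta <- dl_eta %*% t(params$Weta)
  # block t of dH_eta is the gradient at h_{t-1}: shift one block down and
  # drop the h_0 share (the initial state is constant)
  dhs_enc <- matrix(0, M * B, H)
  if (M > 1)
    dhs_enc[seq_len((M - 1) * B), ] <- dH_eta[-seq_len(B), , drop = FALSE]
  bd_enc <- lstm_backward(enc, params$Whe, dhs_enc, dh_last = dhM)
  g$Whe <- bd_enc$dWh
  dG_enc <- bd_enc$dInputs
  g$Wxe <- index_add(g$Wxe, as.vector(X), dG_enc)
  g$be <- colSums(dG_enc)
  out$grads <- g
  out
}

#' Fit the neural predictive rate-distortion estimator
#'
#' Trains the full variational system for one trade-off weight `lambda`: an
#' LSTM encoder mapping the length-M past block to a diagonal Gaussian code
#' (reparameterized sampling, one draw per sequence), an LSTM decoder
#' predicting the future block from the code by teacher forcing, an
#' autoregressive flow modelling the code marginal, and a past-marginal head
#' on the shared encoder trunk used to estimate predictiveness. The training
#' objective is the variational predictive rate-distortion bound
#' `E[ -log P(future | Z) + lambda * KL(P(Z | past) || q(Z)) - log P(past) ]`,
#' minimized with Adam; after each pass the objective is evaluated on the
#' validation set (one fixed code sample per sequence) and optimization stops
#' once it no longer improves, returning the parameters of the best pass.
#'
#' @param train,val disjoint [trajectory_set()]s of sequences of length
#'   `2 * M` (past block then future block).
#' @param lambda trade-off weight in (0, 1).
#' @param config an [nprd_config()].
#' @param seed integer seed governing initialization, shuffling and code
#'   sampling; identical seeds give identical fits.
#' @param verbose print one line per pass.
#' @return An object of class `nprd`: parameters, config, training log
#'   (`data.frame` with pass index, train and validation objective), and
#'   metadata. Use [nprd_evaluate()] for held-out bounds.
#' @export
nprd <- function(train, val, lambda, config = nprd_config(), seed = 1,
                 verbose = FALSE) {
  stopifnot(inherits(train, "trajectory_set"), inherits(val, "trajectory_set"))
  stopifnot(identical(train$alphabet, val$alphabet))
  L <- ncol(train$seq)
  stopifnot(L %% 2 == 0, ncol(val$seq) == L)
  M <- L %/% 2
  A <- length(train$alphabet)
  k <- config$code_dim
  params <- nprd_init_params(A, config, seed)
  adam <- adam_init(params)
  n <- nrow(train$seq)
  nb <- ceiling(n / config$batch_size)

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed + 7L)
  val_eps <- matrix(stats::rnorm(nrow(val$seq) * k), nrow(val$seq), k)

  val_obj <- function(p) {
    tot <- 0; nseq <- nrow(val$seq)
    bs <- 2048L
    for (s in seq(1, nseq, by = bs)) {
      idx <- s:min(s + bs - 1L, nseq)
      st <- nprd_step(p, config, val$seq[idx, 1:M, drop = FALSE],
                      val$seq[idx, (M + 1):L, drop = FALSE], lambda,
                      val_eps[idx, , drop = FALSE], A, grad = FALSE)
      tot <- tot + sum(st$obj_i)
    }
    tot / nseq
  }

  best <- list(params = params, obj = Inf, pass = 0)
  log_rows <- list()
  bad <- 0
  for (pass in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tr_obj <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      Bb <- length(idx)
      eps <- matrix(stats::rnorm(Bb * k), Bb, k)
      st <- nprd_step(params, config, train$seq[idx, 1:M, drop = FALSE],
                      train$seq[idx, (M + 1):L, drop = FALSE], lambda, eps, A)
      if (!is.finite(st$objective))
        stop("non-finite training objective at pass ", pass, ", batch ", b,
             " (lr = ", config$lr, "): divergence")
      tr_obj <- tr_obj + st$objective * Bb
      upd <- adam_step(params, st$grads, adam,
                       lr = config$lr *
                         (if (is.null(config$lr_decay)) 1
                          else config$lr_decay)^(pass - 1),
                       clip = config$clip)
      params <- upd$params; adam <- upd$state
    }
    vo <- val_obj(params)
    if (!is.finite(vo))
      stop("non-finite validation objective at pass ", pass,
           " (lr = ", config$lr, "): divergence")
    improved <- vo < best$obj
    log_rows[[pass]] <- data.frame(pass = pass, train_objective = tr_obj / n,
                                   val_objective = vo, best = improved)
    if (verbose)
      cat(sprintf("pass %d: train %.4f val %.4f%s\n", pass, tr_obj / n, vo,
                  if (improved) " *" else ""))
    if (improved) {
      best <- list(params = params, obj = vo, pass = pass)
      bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config,
                 alphabet = train$alphabet, horizon = M, lambda = lambda,
                 seed = seed, best_pass = best$pass, val_objective = best$obj,
                 log = do.call(rbind, log_rows)),
            class = "nprd")
}

#' @export
print.nprd <- function(x, ...) {
  cat("NPRD bundle: M =", x$horizon, ", lambda =", format(x$lambda, digits = 4),
      ", alphabet size", length(x$alphabet), "\n")
  cat("hidden =", x$config$hidden, ", code dim =", x$config$code_dim,
      "; best pass", x$best_pass, "of", nrow(x$log),
      "(val objective", format(x$val_objective, digits = 5), "nats)\n")
  invisible(x)
}

#' Predict from a fitted bundle
#'
#' `type = "code"` returns the Gaussian code parameters for past blocks
#' (see [encode_past()]); `"future_nll"` scores future blocks given codes
#' (see [future_nll()]); `"past_nll"` scores past blocks under the
#' past-marginal head.
#'
#' @param object a fitted [nprd()] bundle.
#' @param newdata a [trajectory_set()], integer matrix, or character vector.
#' @param type what to compute.
#' @param code codes for `type = "future_nll"`; defaults to the encoder
#'   means of the corresponding past blocks.
#' @param ... ignored.
#' @return See the underlying functions.
#' @export
predict.nprd <- function(object, newdata,
                         type = c("code", "future_nll", "past_nll"),
                         code = NULL, ...) {
  type <- match.arg(type)
  M <- object$horizon
  x <- if (inherits(newdata, "trajectory_set")) newdata$seq else newdata
  switch(type,
    code = encode_past(object, x),
    past_nll = past_nll(object, x),
    future_nll = {
      xm <- as_past_matrix(object, x)
      if (is.null(code)) {
        stopifnot(ncol(xm) == 2 * M)
        code <- encode_past(object, xm[, seq_len(M), drop = FALSE])$mu
      }
      future_nll(object, code, xm[, (ncol(xm) - M + 1):ncol(xm), drop = FALSE])
    })
}

#' @export
summary.nprd <- function(object, ...) {
  print(object)
  cat("\nTraining log:\n")
  print(object$log, row.names = FALSE)
  invisible(object)
}

as_past_matrix <- function(bundle, past) {
  if (inherits(past, "trajectory_set")) past <- past$seq
  if (is.character(past)) past <- matrix(match(past, bundle$alphabet), nrow = 1)
  p <- as.matrix(past)
  if (anyNA(p)) stop("symbol outside the bundle vocabulary")
  storage.mode(p) <- "integer"
  p
}

#' Encode past blocks into Gaussian code parameters
#'
#' Deterministic map from a past block to the mean and scale of the Gaussian
#' code distribution.
#'
#' @param bundle a fitted [nprd()] object.
#' @param past character vector (one past block), integer matrix (one row
#'   per block), or a [trajectory_set()] whose first `M` columns are used.
#' @return List with matrices `mu` and `sigma` (one row per input block).
#' @export
encode_past <- function(bundle, past) {
  p <- as_past_matrix(bundle, past)
  M <- bundle$horizon
  if (ncol(p) > M) p <- p[, seq_len(M), drop = FALSE]
  stopifnot(ncol(p) == M)
  cfg <- bundle$config; B <- nrow(p)
  enc_all <- bundle$params$Wxe[as.vector(p), , drop = FALSE]
  enc <- lstm_forward(enc_all, bundle$params$Whe, B, M,
                      bias = bundle$params$be)
  hM <- block_rows(enc$Hs, M + 1L, B)
  mu <- hM %*% bundle$params$Wmu + rep(bundle$params$bmu, each = B)
  sraw <- hM %*% bundle$params$Wsg + rep(bundle$params$bsg, each = B)
  list(mu = mu, sigma = encoder_scale(sraw, cfg))
}

#' Draw reparameterized code samples
#'
#' `z = mu + sigma * eps` with `eps` standard normal.
#'
#' @param params list with `mu` and `sigma` matrices (from [encode_past()]).
#' @param seed integer seed.
#' @return Matrix of codes, one row per input block.
#' @export
sample_code <- function(params, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  mu <- as.matrix(params$mu); sigma <- as.matrix(params$sigma)
  mu + sigma * matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
}

#' Teacher-forced negative log-likelihood of future blocks
#'
#' `-sum_t log P(x_t | x_{<t}, Z)` under the decoder, conditioning each step
#' on the code and the true preceding future symbols only (which preserves
#' the Markov structure of the predictive code).
#'
#' @param bundle a fitted [nprd()] object.
#' @param code matrix of codes (one row per sequence).
#' @param future character vector (one block) or integer matrix of future
#'   blocks.
#' @return Numeric vector of per-sequence NLL in nats.
#' @export
future_nll <- function(bundle, code, future) {
  f <- as_past_matrix(bundle, future)
  M <- bundle$horizon
  if (ncol(f) > M) f <- f[, (ncol(f) - M + 1):ncol(f), drop = FALSE]
  z <- if (is.null(dim(code))) matrix(code, nrow = 1) else as.matrix(code)
  cfg <- bundle$config; B <- nrow(f); A <- length(bundle$alphabet)
  stopifnot(nrow(z) == B)
  zW <- z %*% bundle$params$Wzd
  inp_all <- c(rep(A + 1L, B), as.vector(f[, -M, drop = FALSE]))
  dec_all <- bundle$params$Wxd[inp_all, , drop = FALSE]
  dec <- lstm_forward(dec_all, bundle$params$Whd, B, M,
                      bias = bundle$params$bd, extra = zW)
  Hdec <- dec$Hs[-seq_len(B), , drop = FALSE]
  logits <- Hdec %*% bundle$params$Wod + rep(bundle$params$bod, each = B * M)
  maskf <- matrix(1, B, M)
  if (!is.na(cfg$pad_symbol)) maskf[f == cfg$pad_symbol] <- 0
  nll <- softmax_xent(logits, as.vector(f))$nll * as.vector(maskf)
  rowSums(matrix(nll, B, M))
}

#' Autoregressive negative log-likelihood of past blocks
#'
#' `-log P_eta(past)` under the past-marginal head of the shared encoder
#' trunk.
#'
#' @param bundle a fitted [nprd()] object.
#' @param past as in [encode_past()].
#' @return Numeric vector of per-sequence NLL in nats.
#' @export
past_nll <- function(bundle, past) {
  p <- as_past_matrix(bundle, past)
  M <- bundle$horizon
  if (ncol(p) > M) p <- p[, seq_len(M), drop = FALSE]
  cfg <- bundle$config; B <- nrow(p)
  enc_all <- bundle$params$Wxe[as.vector(p), , drop = FALSE]
  enc <- lstm_forward(enc_all, bundle$params$Whe, B, M,
                      bias = bundle$params$be)
  Henc <- enc$Hs[seq_len(M * B), , drop = FALSE]
  logits <- Henc %*% bundle$params$Weta +
    rep(bundle$params$beta_b, each = B * M)
  maskp <- matrix(1, B, M)
  if (!is.na(cfg$pad_symbol)) maskp[p == cfg$pad_symbol] <- 0
  nll <- softmax_xent(logits, as.vector(p))$nll * as.vector(maskp)
  rowSums(matrix(nll, B, M))
}

#' Monte-Carlo estimate of the training objective on a batch
#'
#' One reparameterized code sample per sequence; unbiased estimate of the
#' full variational objective (future NLL + lambda * rate term + past NLL).
#'
#' @param bundle a fitted [nprd()] object.
#' @param batch a [trajectory_set()] of sequences of length `2 * M`.
#' @param lambda trade-off weight (defaults to the bundle's).
#' @param seed seed for the code samples.
#' @return Scalar objective in nats.
#' @export
batch_objective <- function(bundle, batch, lambda = bundle$lambda, seed = 1) {
  M <- bundle$horizon
  stopifnot(ncol(batch$seq) == 2 * M)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(batch$seq) * bundle$config$code_dim),
                nrow(batch$seq), bundle$config$code_dim)
  st <- nprd_step(bundle$params, bundle$config, batch$seq[, 1:M, drop = FALSE],
                  batch$seq[, (M + 1):(2 * M), drop = FALSE], lambda, eps,
                  length(bundle$alphabet), grad = FALSE)
  if (!is.finite(st$objective)) stop("non-finite batch objective")
  st$objective
}

#' Held-out variational bounds on rate, loss and predictiveness
#'
#' For each test sequence one code is sampled from the encoder; the rate
#' estimate is the mean of `log p_N(mu,sigma)(z) - log q(z)` (an unbiased
#' Monte-Carlo estimate of an upper bound on the true rate), the loss
#' estimate is the mean teacher-forced future NLL (an upper bound on the
#' conditional entropy of the future given the code), and predictiveness is
#' the past-marginal cross-entropy minus the loss (by stationarity the past
#' and future block laws coincide). Standard errors come from the
#' per-sequence variance.
#'
#' @param bundle a fitted [nprd()] object.
#' @param test a [trajectory_set()] disjoint from training data.
#' @param seed seed for the code samples.
#' @param samples code samples per sequence to average (default 1).
#' @return Object of class `nprd_report`: a [prd_point()] plus `eta_ce`
#'   (cross-entropy of the past-marginal head, nats/block) and `n_test`.
#' @export
nprd_evaluate <- function(bundle, test, seed = 1, samples = 1) {
  M <- bundle$horizon; L <- ncol(test$seq)
  stopifnot(L == 2 * M)
  A <- length(bundle$alphabet); k <- bundle$config$code_dim
  n <- nrow(test$seq)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  rate_i <- matrix(0, n, samples); loss_i <- rate_i; past_i <- rate_i
  bs <- 2048L
  for (s in seq_len(samples)) {
    eps <- matrix(stats::rnorm(n * k), n, k)
    for (st0 in seq(1, n, by = bs)) {
      idx <- st0:min(st0 + bs - 1L, n)
      st <- nprd_step(bundle$params, bundle$config,
                      test$seq[idx, 1:M, drop = FALSE],
                      test$seq[idx, (M + 1):L, drop = FALSE],
                      bundle$lambda, eps[idx, , drop = FALSE], A, grad = FALSE)
      rate_i[idx, s] <- st$lpg - st$logq
      loss_i[idx, s] <- st$fut_nll
      past_i[idx, s] <- st$past_nll
    }
  }
  r <- rowMeans(rate_i); l <- rowMeans(loss_i); p <- rowMeans(past_i)
  d <- p - l
  pt <- prd_point(bundle$lambda, rate = mean(r), loss = mean(l),
                  predictiveness = mean(d),
                  se_rate = stats::sd(r) / sqrt(n),
                  se_loss = stats::sd(l) / sqrt(n),
                  se_predictiveness = stats::sd(d) / sqrt(n))
  structure(list(point = pt, eta_ce = mean(p), n_test = n,
                 lambda = bundle$lambda), class = "nprd_report")
}

#' @export
print.nprd_report <- function(x, ...) {
  print(x$point)
  cat("past-marginal cross-entropy:", format(x$eta_ce, digits = 5),
      "nats/block on", x$n_test, "test sequences\n")
  invisible(x)
}

#' Save / load a fitted bundle
#'
#' The bundle (parameters, config, vocabulary, metadata) is written to a
#' directory with a format version tag.
#'
#' @param bundle a fitted [nprd()] object.
#' @param dir directory path.
#' @return `save_nprd`: `dir`, invisibly. `load_nprd`: the bundle.
#' @export
save_nprd <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(unclass(bundle), file.path(dir, "bundle.rds"))
  writeLines(c("format: nprd-bundle", "version: 1"),
             file.path(dir, "VERSION"))
  invisible(dir)
}

#' @rdname save_nprd
#' @export
load_nprd <- function(dir) {
  v <- readLines(file.path(dir, "VERSION"))
  if (!any(grepl("nprd-bundle", v))) stop("not an nprd bundle directory")
  structure(readRDS(file.path(dir, "bundle.rds")), class = "nprd")
}
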