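#' Autoregressive flow model of the code marginal
#'
#' The approximate code marginal `q(Z)` is modelled autoregressively over the
#' code dimensions: each conditional `q(z_d | z_{<d})` is a mixture of `C`
#' Gaussians whose logits, means and log-scales are affine functions of the
#' preceding dimensions. Each conditional is a strictly monotone invertible
#' transform of a base variable (through the mixture CDF), so the model is an
#' autoregressive normalizing flow with exactly tractable log-density. With
#' all parameters zero the components coincide and the density is exactly
#' standard normal (the identity initialization).
#'
#' @param k code dimension.
#' @param n_components number of mixture components per conditional.
#' @param init `"identity"` (exact standard normal) or `"jitter"` (component
#'   mean offsets perturbed by `N(0, 0.1^2)` noise to break the symmetry
#'   between components before training).
#' @param seed seed for the jitter.
#' @return An object of class `nprd_flow`.
#' @export
nprd_flow <- function(k, n_components = 6, init = c("identity", "jitter"),
                      seed = 1) {
  init <- match.arg(init)
  C <- n_components
  fl <- list(k = k, C = C,
             Fp = array(0, c(k, k, C)), Fpb = matrix(0, k, C),
             Fm = array(0, c(k, k, C)), Fmb = matrix(0, k, C),
             Fs = array(0, c(k, k, C)), Fsb = matrix(0, k, C))
  if (init == "jitter") {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
    fl$Fmb <- matrix(stats::rnorm(k * C, sd = 0.1), k, C)
  }
  class(fl) <- "nprd_flow"
  fl
}

flow_mask <- function(k) {
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- 1          # row d conditions on dimensions j < d
  m
}

# Core density computation. z: B x k. Returns per-item log-density; with
# grad = TRUE also the gradient w.r.t. z and the flow parameters of
# sum_b w_b * logq_b. Internally arrays are collapsed to (B*k) x C matrices.
flow_logq <- function(flow, z, grad = FALSE, w = 1) {
  k <- flow$k; C <- flow$C
  B <- nrow(z)
  mask <- flow_mask(k)
  Pv <- matrix(0, B * k, C); Mv <- Pv; Sv <- Pv
  for (cc in seq_len(C)) {
    Pv[, cc] <- z %*% t(flow$Fp[, , cc] * mask) + rep(flow$Fpb[, cc], each = B)
    Mv[, cc] <- z %*% t(flow$Fm[, , cc] * mask) + rep(flow$Fmb[, cc], each = B)
    Sv[, cc] <- z %*% t(flow$Fs[, , cc] * mask) + rep(flow$Fsb[, cc], each = B)
  }
  rowmax <- function(m) do.call(pmax, as.data.frame(m))
  pm <- rowmax(Pv)
  logw <- (Pv - pm) - log(rowSums(exp(Pv - pm)))       # log mixture weights
  zv <- as.vector(z)                                   # B*k
  ee <- (zv - Mv) / exp(Sv)
  lj <- logw - 0.5 * log(2 * pi) - Sv - 0.5 * ee^2
  lm <- rowmax(lj)
  lq_d <- lm + log(rowSums(exp(lj - lm)))              # per (item, dim)
  logq <- rowSums(matrix(lq_d, B, k))
  if (!grad) return(list(logq = logq))

  wt <- if (length(w) == 1) rep(w, B) else w
  wrep <- rep(wt, k)                                   # per (item, dim)
  r <- exp(lj - lq_d)                                  # responsibilities
  Wm <- exp(logw)
  dP <- (r - Wm) * wrep
  dM <- (r * ee / exp(Sv)) * wrep
  dS <- (r * (ee^2 - 1)) * wrep
  dz <- -matrix(rowSums(dM), B, k)                     # direct argument term
  gFp <- array(0, c(k, k, C)); gFm <- gFp; gFs <- gFp
  gFpb <- matrix(0, k, C); gFmb <- gFpb; gFsb <- gFpb
  for (cc in seq_len(C)) {
    dPc <- matrix(dP[, cc], B, k)
    dMc <- matrix(dM[, cc], B, k)
    dSc <- matrix(dS[, cc], B, k)
    dz <- dz + dPc %*% (flow$Fp[, , cc] * mask) +
      dMc %*% (flow$Fm[, , cc] * mask) +
      dSc %*% (flow$Fs[, , cc] * mask)
    gFp[, , cc] <- crossprod(dPc, z) * mask
    gFm[, , cc] <- crossprod(dMc, z) * mask
    gFs[, , cc] <- crossprod(dSc, z) * mask
    gFpb[, cc] <- colSums(dPc)
    gFmb[, cc] <- colSums(dMc)
    gFsb[, cc] <- colSums(dSc)
  }
  list(logq = logq, dz = dz,
       grads = list(Fp = gFp, Fpb = gFpb, Fm = gFm, Fmb = gFmb,
                    Fs = gFs, Fsb = gFsb))
}

#' Log-density of the flow at given code points
#'
#' @param flow an [nprd_flow()] (or a fitted `nprd` bundle, whose flow is
#'   extracted).
#' @param code numeric vector of length `k` or a matrix with one code per
#'   row.
#' @return Numeric vector of log-densities in nats.
#' @export
flow_log_density <- function(flow, code) {
  if (inherits(flow, "nprd")) flow <- bundle_flow(flow)
  stopifnot(inherits(flow, "nprd_flow"))
  z <- if (is.null(dim(code))) matrix(code, nrow = 1) else as.matrix(code)
  stopifnot(ncol(z) == flow$k)
  out <- flow_logq(flow, z)$logq
  if (any(!is.finite(out)))
    stop("non-finite flow log-density: parameter blow-up")
  out
}

#' CDF of a one-dimensional flow
#'
#' Only defined for `k = 1`; useful for checking invertibility (the CDF of a
#' valid flow is strictly nondecreasing).
#'
#' @param flow an [nprd_flow()] with `k = 1`.
#' @param x numeric vector of evaluation points.
#' @return CDF values.
#' @export
flow_cdf <- function(flow, x) {
  stopifnot(flow$k == 1L)
  lw <- flow$Fpb[1, ] - logsumexp(flow$Fpb[1, ])
  w <- exp(lw)
  vapply(x, function(xx)
    sum(w * stats::pnorm(xx, mean = flow$Fmb[1, ], sd = exp(flow$Fsb[1, ]))),
    0)
}
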