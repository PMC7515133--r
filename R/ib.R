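#' Information-bottleneck Blahut-Arimoto iteration
#'
#' Finds a (locally) optimal soft codebook for the objective
#' `H[target | Z] + lambda * I[source, Z]` on a finite joint table: the
#' finite-horizon predictive rate-distortion problem when the sources are
#' causal states or past blocks and the targets are future blocks. The
#' iteration alternates the self-consistent updates
#' `P(z|x) propto q(z) exp(-KL(p(y|x) || p(y|z)) / lambda)`,
#' `q(z) = sum_x p(x) P(z|x)`, and the Bayes decoder `p(y|z)`. The objective
#' is nonincreasing across sweeps within a run (checked); several random
#' restarts guard against local optima and the best solution is returned.
#'
#' For `lambda >= 1` the optimum is the trivial zero-rate code; for
#' `lambda -> 0` the code refines toward one codeword per distinct
#' conditional future distribution (the causal states).
#'
#' @param joint a [joint_table()].
#' @param lambda trade-off weight, > 0; larger values penalize rate harder.
#' @param K number of codewords available (>= 1).
#' @param tol convergence threshold on the relative objective change.
#' @param max_iter maximum sweeps per restart.
#' @param restarts number of random initializations.
#' @param seed integer seed for the restarts.
#' @param init_encoder optional list of row-stochastic encoder matrices used
#'   as additional (warm-start) initializations.
#' @return An object of class `ib_codebook`: list with `encoder`
#'   (`|X| x K`, row-stochastic), `marginal` (`q(z)`), `decoder`
#'   (`K x |Y|`, row-stochastic), `lambda`, and a `point` element with the
#'   achieved `rate`, `loss`, `predictiveness` and `objective` (all nats),
#'   plus `converged` and `monotone` flags.
#' @examples
#' j <- causal_future_joint(build_machine("even"), 5)
#' fit <- ib_blahut_arimoto(j, lambda = 0.2, K = 4, seed = 1)
#' fit$point
#' @export
ib_blahut_arimoto <- function(joint, lambda, K, tol = 1e-10, max_iter = 5000,
                              restarts = 10, seed = 1, init_encoder = NULL) {
  stopifnot(lambda > 0, K >= 1)
  p <- unclass(joint)
  px <- rowSums(p)
  keep <- px > 0
  pfull_rows <- length(px)
  pxk <- px[keep]
  pyx <- p[keep, , drop = FALSE] / pxk       # conditional p(y|x)
  negH <- rowSums(ifelse(pyx > 0, pyx * log(pyx), 0))  # -H[Y|X=x]
  X <- nrow(pyx)

  inits <- list()
  if (!is.null(init_encoder)) {
    for (E in init_encoder) {
      E <- as.matrix(E)
      if (nrow(E) == pfull_rows) E <- E[keep, , drop = FALSE]
      if (ncol(E) < K) E <- cbind(E, matrix(1e-12, nrow(E), K - ncol(E)))
      inits <- c(inits, list(E[, seq_len(K), drop = FALSE] /
                               rowSums(E[, seq_len(K), drop = FALSE])))
    }
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    E <- matrix(stats::rexp(X * K), X, K)
    inits <- c(inits, list(E / rowSums(E)))
  }

  best <- NULL
  for (E0 in inits) {
    run <- ba_run(E0, pxk, pyx, negH, lambda, tol, max_iter)
    if (is.null(best) || run$objective < best$objective - 1e-15) best <- run
  }

  enc <- best$enc
  q <- as.vector(crossprod(enc, pxk))
  dec <- ba_decoder(enc, pxk, pyx, q)
  # re-expand encoder over zero-probability sources (assign their row to the
  # closest conditional? they carry no mass; use marginal q for definiteness)
  enc_full <- matrix(rep(q, each = pfull_rows), pfull_rows, K)
  enc_full[keep, ] <- enc
  enc_full <- enc_full / rowSums(enc_full)
  rate <- max(ib_rate(enc, pxk, q), 0)   # clip float negatives at the collapse
  loss <- ib_loss(enc, pxk, pyx, dec)
  pred <- entropy_with_zeros(colSums(p)) - loss
  structure(list(
    encoder = enc_full, marginal = q, decoder = dec, lambda = lambda,
    point = prd_point(lambda, rate, loss, pred),
    converged = best$converged, monotone = best$monotone,
    sweeps = best$sweeps, source_kept = keep
  ), class = "ib_codebook")
}

entropy_with_zeros <- function(p) entropy_nats(p)

ba_decoder <- function(enc, px, pyx, q) {
  dec <- crossprod(enc * px, pyx)            # p(z, y)
  ok <- q > 1e-300
  dec[ok, ] <- dec[ok, , drop = FALSE] / q[ok]
  dec[!ok, ] <- 1 / ncol(pyx)
  dec
}

ib_rate <- function(enc, px, q) {
  lq <- log(pmax(q, 1e-300))
  pos <- enc > 0
  w <- (enc * px)
  sum(w[pos] * (log(enc[pos]) - lq[col(enc)[pos]]))
}

ib_loss <- function(enc, px, pyx, dec) {
  ld <- log(pmax(dec, 1e-300))
  joint_zy <- crossprod(enc * px, pyx)
  -sum(joint_zy * ld)
}

ba_objective <- function(enc, px, pyx, q, dec, lambda) {
  ib_loss(enc, px, pyx, dec) + lambda * ib_rate(enc, px, q)
}

ba_run <- function(enc, px, pyx, negH, lambda, tol, max_iter) {
  K <- ncol(enc)
  obj_prev <- Inf
  monotone <- TRUE
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    q <- as.vector(crossprod(enc, px))
    dec <- ba_decoder(enc, px, pyx, q)
    ld <- log(pmax(dec, 1e-300))
    # KL(p(y|x) || p(y|z)) = -H[Y|x] - sum_y p(y|x) log dec[z,y]
    D <- negH - pyx %*% t(ld)                # X x K
    le <- sweep(-D / lambda, 2, log(pmax(q, 1e-300)), `+`)
    le <- le - apply(le, 1, max)
    enc_new <- exp(le)
    enc_new <- enc_new / rowSums(enc_new)
    obj <- ba_objective(enc_new, px, pyx,
                        q = as.vector(crossprod(enc_new, px)),
                        dec = ba_decoder(enc_new, px, pyx,
                                         as.vector(crossprod(enc_new, px))),
                        lambda = lambda)
    if (obj > obj_prev + 1e-9 * max(1, abs(obj_prev))) monotone <- FALSE
    delta <- max(abs(enc_new - enc))
    enc <- enc_new
    # require both a settled objective and a settled encoder: near the
    # zero-rate fixed point the objective flattens while the encoder rows
    # are still contracting; the residual rate scales quadratically in the
    # row change, so 1e-7 leaves it far below any reported precision
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(1, abs(obj_prev)) &&
        delta <= 1e-7) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
    if (it >= max_iter) break
  }
  list(enc = enc, objective = obj_prev, converged = converged,
       monotone = monotone, sweeps = it)
}

#' @export
print.ib_codebook <- function(x, ...) {
  cat("IB codebook (lambda = ", format(x$lambda, digits = 4), ", K = ",
      ncol(x$encoder), ")\n", sep = "")
  print(x$point)
  cat(if (x$converged) "converged" else "NOT converged",
      "after", x$sweeps, "sweeps;",
      effective_codewords(x), "effective codeword(s)\n")
  invisible(x)
}

#' A point on a predictive rate-distortion curve
#'
#' @param lambda trade-off weight.
#' @param rate `I[source, Z]` in nats.
#' @param loss prediction loss `H[target | Z]` in nats.
#' @param predictiveness `I[Z, target]` in nats.
#' @param se_rate,se_loss,se_predictiveness optional Monte-Carlo standard
#'   errors (NA for exact computations).
#' @param converged optional convergence flag.
#' @return One-row `data.frame` of class `prd_point` with an `objective`
#'   column equal to `loss + lambda * rate`.
#' @export
prd_point <- function(lambda, rate, loss, predictiveness,
                      se_rate = NA_real_, se_loss = NA_real_,
                      se_predictiveness = NA_real_, converged = TRUE) {
  out <- data.frame(lambda = lambda, rate = rate, loss = loss,
                    predictiveness = predictiveness,
                    objective = loss + lambda * rate,
                    se_rate = se_rate, se_loss = se_loss,
                    se_predictiveness = se_predictiveness,
                    converged = converged)
  class(out) <- c("prd_point", class(out))
  out
}

#' Count effective codewords of a fitted codebook
#'
#' Codewords with marginal weight below `weight_tol` are dropped and
#' surviving codewords whose decoder rows differ by total-variation distance
#' below `merge_tol` are merged, separating numerical duplicates from
#' genuinely distinct codewords.
#'
#' @param codebook an `ib_codebook`.
#' @param weight_tol minimum marginal probability for a codeword to count.
#' @param merge_tol total-variation threshold below which decoder rows are
#'   considered the same codeword.
#' @return Integer count of effective codewords.
#' @export
effective_codewords <- function(codebook, weight_tol = 1e-4, merge_tol = 1e-3) {
  keep <- which(codebook$marginal >= weight_tol)
  if (!length(keep)) return(0L)
  dec <- codebook$decoder[keep, , drop = FALSE]
  groups <- integer(0)
  reps <- list()
  for (i in seq_len(nrow(dec))) {
    placed <- FALSE
    for (g in seq_along(reps)) {
      if (0.5 * sum(abs(dec[i, ] - reps[[g]])) < merge_tol) {
        placed <- TRUE; break
      }
    }
    if (!placed) reps[[length(reps) + 1L]] <- dec[i, ]
  }
  length(reps)
}

#' Analytic predictive rate-distortion curve of a machine
#'
#' Runs the information-bottleneck iteration on the exact joint of causal
#' state and length-`horizon` future block, for each value of the trade-off
#' grid. Successive grid values (visited in increasing `lambda` order) are
#' warm-started from the previous solution in addition to fresh random
#' restarts.
#'
#' @param machine a [prd_machine()].
#' @param horizon future block length M (default 15).
#' @param lambda_grid increasing vector of trade-off weights in (0, Inf).
#' @param K codewords; default `length(machine$states) + 2` (the optimum
#'   needs at most one codeword per causal state, slack aids optimization).
#' @param restarts,tol,max_iter,seed passed to [ib_blahut_arimoto()].
#' @return A `data.frame` of class `prd_curve`: one [prd_point()] row per
#'   lambda, with a `pareto_ok` attribute flagging monotonicity violations
#'   beyond 1e-6.
#' @export
analytic_prd_curve <- function(machine, horizon = 15, lambda_grid,
                               K = length(machine$states) + 2L,
                               restarts = 10, tol = 1e-10, max_iter = 5000,
                               seed = 1) {
  stopifnot(all(lambda_grid > 0))
  joint <- causal_future_joint(machine, horizon, labels = FALSE)
  ord <- order(lambda_grid)
  fits <- vector("list", length(lambda_grid))
  prev <- NULL
  for (i in ord) {
    fits[[i]] <- ib_blahut_arimoto(
      joint, lambda = lambda_grid[i], K = K, tol = tol, max_iter = max_iter,
      restarts = restarts, seed = seed + i,
      init_encoder = if (is.null(prev)) NULL else list(prev))
    prev <- fits[[i]]$encoder
  }
  pts <- do.call(rbind, lapply(fits, function(f) {
    p <- f$point; p$converged <- f$converged; p
  }))
  pts <- pts[order(pts$lambda), ]
  ok <- all(diff(pts$rate) <= 1e-6) && all(diff(pts$predictiveness) <= 1e-6)
  attr(pts, "pareto_ok") <- ok
  attr(pts, "codebooks") <- fits
  class(pts) <- c("prd_curve", "data.frame")
  pts
}

#' Write a rate-distortion curve as TSV
#'
#' Columns: `lambda`, `rate_nats`, `loss_nats`, `predictiveness_nats`,
#' `objective_nats`, `converged`.
#'
#' @param curve a `prd_curve` or any data.frame of [prd_point()] rows.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  out <- data.frame(lambda = curve$lambda, rate_nats = curve$rate,
                    loss_nats = curve$loss,
                    predictiveness_nats = curve$predictiveness,
                    objective_nats = curve$objective,
                    converged = curve$converged)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
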