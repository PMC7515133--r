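#' Pareto frontier of rate-distortion runs
#'
#' Keeps the runs not dominated by any other (no other run has both lower
#' rate and higher predictiveness), sorted by rate. Piecewise-linear
#' interpolation between the surviving points defines the reported trade-off
#' curve.
#'
#' @param runs data.frame with at least `rate` and `predictiveness` columns
#'   (e.g. stacked [prd_point()] rows or a [prd_sweep()] result).
#' @return The dominant subset, sorted by rate, of class `prd_frontier`.
#' @export
pareto_frontier <- function(runs) {
  stopifnot(nrow(runs) >= 1)
  ord <- order(runs$rate, -runs$predictiveness)
  runs <- runs[ord, , drop = FALSE]
  best <- -Inf
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (runs$predictiveness[i] > best + 1e-12) {
      keep[i] <- TRUE
      best <- runs$predictiveness[i]
    }
  }
  out <- runs[keep, , drop = FALSE]
  class(out) <- unique(c("prd_frontier", class(out)))
  out
}

#' Interpolate a frontier at given rates
#'
#' Linear interpolation in (rate, predictiveness), anchored at the origin:
#' the zero-rate code achieves exactly zero predictiveness, so frontier
#' points dominated by the origin (negative Monte-Carlo predictiveness
#' estimates) are dropped. Rates beyond the largest frontier rate return the
#' maximum predictiveness.
#'
#' @param frontier a [pareto_frontier()] result.
#' @param rate numeric vector of rates.
#' @return Predictiveness values.
#' @export
frontier_predictiveness <- function(frontier, rate) {
  x <- c(0, frontier$rate)
  y <- c(0, frontier$predictiveness)
  keep <- !duplicated(x) & y >= cummax(c(0, y[-length(y)]))
  keep[1] <- TRUE
  stats::approx(x[keep], y[keep], xout = rate, rule = 2)$y
}

#' Fit the superlinear rate ansatz
#'
#' Fits the two-parameter law `R = alpha * log(1/lambda)^beta` to (lambda,
#' rate) pairs and, given it, `P = E0 - alpha * beta * Gamma(beta,
#' (R/alpha)^(1/beta))` to (rate, predictiveness) pairs, where `Gamma` is the
#' upper incomplete gamma function; `E0` is the asymptote of predictiveness
#' (the mutual information between past and future blocks). Initial
#' estimates come from regressing `log R` on `log log(1/lambda)` (exact for
#' noiseless points) and a closed-form `E0`; all three parameters are then
#' refined jointly by least squares on both residual sets.
#'
#' @param runs data.frame with columns `lambda`, `rate`, `predictiveness`
#'   spanning at least 5 distinct lambdas.
#' @return Object of class `prd_ansatz`: `alpha > 0`, `beta > 1`, `E0 >= 0`,
#'   residual sum of squares.
#' @export
fit_ansatz <- function(runs) {
  runs <- runs[runs$lambda > 0 & runs$lambda < 1 & runs$rate > 0, , drop = FALSE]
  if (nrow(runs) < 5) stop("need at least 5 frontier points with positive rate")
  ll <- log(log(1 / runs$lambda))
  if (max(ll) - min(ll) < 0.2)
    stop("degenerate lambda spread: widen the lambda range")
  cf <- unname(stats::lm.fit(cbind(1, ll), log(runs$rate))$coefficients)
  alpha0 <- exp(cf[1]); beta0 <- max(cf[2], 1.0001)
  E00 <- mean(runs$predictiveness +
                alpha0 * beta0 * inc_gamma_upper(beta0, (runs$rate / alpha0)^(1 / beta0)))
  objfn <- function(th) {
    a <- exp(th[1]); b <- 1 + exp(th[2]); e0 <- th[3]
    r_hat <- a * log(1 / runs$lambda)^b
    p_hat <- e0 - a * b * inc_gamma_upper(b, (runs$rate / a)^(1 / b))
    sum((log(r_hat) - log(runs$rate))^2) + sum((p_hat - runs$predictiveness)^2)
  }
  opt <- stats::optim(c(log(alpha0), log(beta0 - 1), E00), objfn,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  out <- list(alpha = exp(opt$par[1]), beta = 1 + exp(opt$par[2]),
              E0 = max(opt$par[3], 0), rss = opt$value,
              n = nrow(runs))
  class(out) <- "prd_ansatz"
  out
}

# upper incomplete gamma Gamma(s, x) = int_x^inf t^(s-1) e^(-t) dt
inc_gamma_upper <- function(s, x) {
  gamma(s) * stats::pgamma(x, shape = s, lower.tail = FALSE)
}

#' @export
print.prd_ansatz <- function(x, ...) {
  cat(sprintf("rate ansatz: R = %.4g * log(1/lambda)^%.4g, E0 = %.4g nats (rss %.3g, n = %d)\n",
              x$alpha, x$beta, x$E0, x$rss, x$n))
  invisible(x)
}

#' Evaluate the fitted ansatz
#'
#' Maps `lambda` to rate through `R = alpha log(1/lambda)^beta` and rate to
#' predictiveness through the incomplete-gamma law. The predictiveness curve
#' is nondecreasing and concave in the rate, with slope `dP/dR =
#' exp(-(R/alpha)^(1/beta))` and limit `E0` as the rate grows.
#'
#' @param fit a [fit_ansatz()] result.
#' @param value lambda values (`which = "from-lambda"`) or rates
#'   (`which = "from-rate"`).
#' @param which input interpretation.
#' @return data.frame with columns `lambda` (NA if unknown), `rate`,
#'   `predictiveness`.
#' @export
ansatz_predict <- function(fit, value, which = c("from-lambda", "from-rate")) {
  which <- match.arg(which)
  if (which == "from-lambda") {
    lambda <- value
    rate <- fit$alpha * log(1 / lambda)^fit$beta
  } else {
    lambda <- NA_real_
    rate <- value
  }
  pred <- fit$E0 - fit$alpha * fit$beta *
    inc_gamma_upper(fit$beta, (rate / fit$alpha)^(1 / fit$beta))
  data.frame(lambda = lambda, rate = rate, predictiveness = pred)
}

#' Project code samples onto their top two principal components
#'
#' Deterministic given the input order: each component's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param codes matrix of code vectors (one per row), at least 3 rows.
#' @return Matrix with columns `PC1`, `PC2` (the second is zero-filled for
#'   one-dimensional codes).
#' @export
pca_codes <- function(codes) {
  codes <- as.matrix(codes)
  stopifnot(nrow(codes) >= 3)
  pc <- stats::prcomp(codes, center = TRUE, scale. = FALSE)
  ncomp <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  proj <- scale(codes, center = pc$center, scale = FALSE) %*% rot
  if (ncomp < 2L) proj <- cbind(proj, 0)
  colnames(proj) <- c("PC1", "PC2")
  proj
}

#' Cluster 2-D code projections, choosing k by silhouette
#'
#' k-means on the projection with the cluster count chosen by the best
#' average silhouette width over `k_range` (k = 1 is selected when the best
#' silhouette is below 0.5, i.e. no real cluster structure).
#'
#' @param proj two-column matrix from [pca_codes()].
#' @param k_range candidate cluster counts (k >= 2 candidates).
#' @param seed seed for k-means starts.
#' @return List with `k`, integer `cluster` labels, `centers`, and the
#'   silhouette scores per candidate.
#' @export
cluster_codes <- function(proj, k_range = 2:5, seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  n <- nrow(proj)
  sil <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  sub <- if (n > 2000) sample.int(n, 2000) else seq_len(n)
  dsub <- as.matrix(stats::dist(proj[sub, , drop = FALSE]))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k >= n) next
    km <- stats::kmeans(proj, centers = k, nstart = 10, iter.max = 100)
    fits[[i]] <- km
    sil[i] <- mean_silhouette(dsub, km$cluster[sub])
  }
  best <- which.max(sil)
  if (!length(best) || is.na(sil[best]) || sil[best] < 0.5) {
    return(list(k = 1L, cluster = rep(1L, n),
                centers = matrix(colMeans(proj), 1), silhouette = sil,
                k_range = k_range))
  }
  list(k = k_range[best], cluster = fits[[best]]$cluster,
       centers = fits[[best]]$centers, silhouette = sil, k_range = k_range)
}

mean_silhouette <- function(d, cl) {
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(NA_real_)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- cl == cl[i]; same[i] <- FALSE
    a <- if (any(same)) mean(d[i, same]) else 0
    b <- min(vapply(ks[ks != cl[i]], function(k2) mean(d[i, cl == k2]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster-transition map under appending one symbol
#'
#' For each (cluster, symbol) with machine-positive probability, shifts each
#' past one step by appending the symbol, re-encodes the shifted past, and
#' records the majority destination cluster (ties broken toward the larger
#' count). Pasts whose causal state is ambiguous at this horizon can be
#' excluded. When the code clusters track the causal states, the resulting
#' table is isomorphic to the machine's transition diagram.
#'
#' @param bundle a fitted [nprd()] object.
#' @param pasts integer matrix of past blocks (one per row).
#' @param clusters integer cluster labels for `pasts` (from
#'   [cluster_codes()]).
#' @param centers cluster centers in PCA space.
#' @param proj_fn function mapping codes to the same 2-D space as `centers`
#'   (e.g. a closure around the [pca_codes()] rotation).
#' @param keep optional logical vector: which pasts enter the majority count
#'   (use to exclude state-ambiguous pasts).
#' @param valid_append optional logical matrix (pasts x alphabet): whether
#'   appending each symbol to each past has positive probability under the
#'   generating machine; invalid appends are excluded.
#' @param seed seed for the code draws of shifted pasts.
#' @return data.frame with columns `from`, `symbol`, `to`,
#'   `majority_fraction`, `n`.
#' @export
transition_map <- function(bundle, pasts, clusters, centers, proj_fn,
                           keep = NULL, valid_append = NULL, seed = 1) {
  A <- length(bundle$alphabet)
  if (is.null(keep)) keep <- rep(TRUE, nrow(pasts))
  if (is.null(valid_append))
    valid_append <- matrix(TRUE, nrow(pasts), A)
  out <- list()
  for (g in sort(unique(clusters))) {
    for (a in seq_len(A)) {
      idx <- which(clusters == g & keep & valid_append[, a])
      if (!length(idx)) next
      shifted <- cbind(pasts[idx, -1, drop = FALSE], a)
      ep <- encode_past(bundle, shifted)
      zs <- sample_code(ep, seed = seed)
      pr <- proj_fn(zs)
      d2 <- vapply(seq_len(nrow(centers)), function(j)
        rowSums((pr - rep(centers[j, ], each = nrow(pr)))^2), numeric(nrow(pr)))
      dest <- max.col(-matrix(d2, nrow = nrow(pr)))
      tab <- tabulate(dest, nbins = nrow(centers))
      out[[length(out) + 1L]] <- data.frame(
        from = g, symbol = bundle$alphabet[a], to = which.max(tab),
        majority_fraction = max(tab) / sum(tab), n = sum(tab))
    }
  }
  do.call(rbind, out)
}

#' Causal-state membership of finite pasts
#'
#' Tracks the set of machine states consistent with an observed past block
#' (starting from all states with positive stationary probability). Returns
#' the state index when unique, `NA` when the past is ambiguous at this
#' horizon.
#'
#' @param machine a [prd_machine()].
#' @param pasts integer matrix of past blocks.
#' @return Integer vector of state indices (NA = ambiguous).
#' @export
causal_state_of_past <- function(machine, pasts) {
  S <- nrow(machine$emit)
  apply(pasts, 1, function(p) {
    states <- seq_len(S)
    for (a in p) {
      states <- unique(machine$trans[states, a][machine$emit[states, a] > 0])
      states <- states[!is.na(states)]
      if (!length(states)) return(NA_integer_)
    }
    if (length(states) == 1L) states else NA_integer_
  })
}
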