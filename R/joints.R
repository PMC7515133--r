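#' Joint probability tables
#'
#' A `joint_table` is a nonnegative matrix summing to 1, with sources
#' (causal states or past blocks) on the rows and future blocks on the
#' columns. Blocks are ordered with the first symbol most significant.
#'
#' @param p nonnegative numeric matrix summing to 1 (within 1e-10).
#' @param normalize if `TRUE`, rescale `p` to sum to exactly 1.
#' @return An object of class `joint_table` (a matrix).
#' @export
joint_table <- function(p, normalize = FALSE) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("joint_table entries must be nonnegative")
  s <- sum(p)
  if (normalize) p <- p / s
  else if (abs(s - 1) > 1e-10) stop("joint_table must sum to 1 (got ", s, ")")
  class(p) <- c("joint_table", class(p))
  p
}

#' @export
print.joint_table <- function(x, ...) {
  cat("joint_table: ", nrow(x), " source(s) x ", ncol(x), " target(s), I = ",
      format(mutual_information(x), digits = 4), " nats\n", sep = "")
  invisible(x)
}

#' Mutual information of a joint table (nats)
#'
#' Plug-in estimator `I = sum p(x,y) log[p(x,y) / (p(x) p(y))]` with the
#' convention `0 log 0 = 0`.
#'
#' @param joint a [joint_table()] or plain joint probability matrix.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(joint) {
  p <- unclass(joint)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * (log(p[pos]) - log(px[row(p)[pos]]) - log(py[col(p)[pos]])))
}

#' Entropy of a probability vector or table (nats)
#' @param p nonnegative numbers summing to 1.
#' @return Shannon entropy in nats.
#' @export
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

block_labels <- function(alphabet, M) {
  lab <- ""
  for (t in seq_len(M)) lab <- as.vector(t(outer(lab, alphabet, paste0)))
  lab
}

# P(future block of length M | start state s), for every state.
# Returns list of length S of vectors of length A^M, first symbol most
# significant, plus the matching end-state vectors.
unroll_futures <- function(machine, M, want_end = FALSE) {
  S <- nrow(machine$emit); A <- ncol(machine$emit)
  probs <- vector("list", S); ends <- vector("list", S)
  for (s0 in seq_len(S)) {
    p <- 1; st <- s0
    for (t in seq_len(M)) {
      n <- length(p)
      pm <- matrix(0, A, n); sm <- matrix(1L, A, n)
      for (a in seq_len(A)) {
        pa <- p * machine$emit[st, a]
        ta <- machine$trans[st, a]
        ta[is.na(ta) | pa == 0] <- 1L
        pm[a, ] <- pa; sm[a, ] <- ta
      }
      p <- as.vector(pm); st <- as.vector(sm)
    }
    probs[[s0]] <- p
    if (want_end) ends[[s0]] <- st
  }
  if (want_end) list(probs = probs, ends = ends) else probs
}

#' Exact joint of causal state and future block
#'
#' Computes `P(state, future block)` by unrolling the machine's emissions for
#' `horizon` steps from each state, weighting states by the stationary
#' distribution. Row sums equal the stationary probabilities; the mutual
#' information of the table converges (in `horizon`) to the excess entropy
#' captured by the causal states.
#'
#' @param machine a [prd_machine()].
#' @param horizon future block length M; `|alphabet|^M` must not exceed
#'   2e6 columns.
#' @param labels attach block-string dimnames (default `TRUE`; disable for
#'   large tables).
#' @return A [joint_table()] with one row per state.
#' @export
causal_future_joint <- function(machine, horizon, labels = TRUE) {
  A <- ncol(machine$emit)
  if (A^horizon > 2e6)
    stop("horizon too large: |alphabet|^M = ", A^horizon, " exceeds 2e6 targets")
  pi <- stationary_distribution(machine)
  fut <- unroll_futures(machine, horizon)
  p <- do.call(rbind, lapply(seq_along(fut), function(s) pi[s] * fut[[s]]))
  if (labels)
    dimnames(p) <- list(machine$states, block_labels(machine$alphabet, horizon))
  joint_table(p, normalize = TRUE)
}

#' Exact joint of past block and future block
#'
#' Brute-force enumeration of `P(past block, future block)` for blocks of
#' length `horizon` on each side, starting from the stationary distribution.
#' Marginals match the machine's block law; useful as an oracle for testing
#' count-based estimators.
#'
#' @inheritParams causal_future_joint
#' @return A [joint_table()] of size `|alphabet|^M` squared.
#' @export
block_joint_bruteforce <- function(machine, horizon, labels = TRUE) {
  A <- ncol(machine$emit)
  if (A^(2 * horizon) > 2e7)
    stop("horizon too large: |alphabet|^(2M) = ", A^(2 * horizon),
         " cells exceed 2e7")
  pi <- stationary_distribution(machine)
  S <- nrow(machine$emit)
  past <- unroll_futures(machine, horizon, want_end = TRUE)
  fut <- unroll_futures(machine, horizon)
  n <- A^horizon
  J <- matrix(0, n, n)
  for (s0 in seq_len(S)) {
    w <- pi[s0] * past$probs[[s0]]
    e <- past$ends[[s0]]
    for (se in seq_len(S)) {
      idx <- which(w > 0 & e == se)
      if (length(idx))
        J[idx, ] <- J[idx, ] + outer(w[idx], fut[[se]])
    }
  }
  if (labels) {
    lab <- block_labels(machine$alphabet, horizon)
    dimnames(J) <- list(lab, lab)
  }
  joint_table(J, normalize = TRUE)
}

#' Exact block entropy (nats)
#'
#' Entropy of the length-`horizon` block distribution of the stationary
#' process generated by `machine`, via causal-state unrolling.
#'
#' @inheritParams causal_future_joint
#' @return Entropy in nats.
#' @export
block_entropy <- function(machine, horizon) {
  pi <- stationary_distribution(machine)
  fut <- unroll_futures(machine, horizon)
  p <- colSums(do.call(rbind, lapply(seq_along(fut), function(s) pi[s] * fut[[s]])))
  entropy_nats(p)
}
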