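#' Count past/future block pairs
#'
#' Splits each sequence at its midpoint into a length-`horizon` past block
#' (the last M positions of the first half) and a length-`horizon` future
#' block (the first M positions of the second half) and counts the observed
#' pairs. A pseudo-sequence `omega`, standing in for blocks never seen in
#' training, is carried as an extra row and column (zero counts until
#' [smooth_counts()] is applied).
#'
#' @param data a [trajectory_set()].
#' @param horizon block length M; at most half the sequence length.
#' @return An object of class `block_count_table`: fields `counts` (matrix
#'   with the omega row/column last), `horizon`, `alphabet`.
#' @export
count_blocks <- function(data, horizon) {
  L <- ncol(data$seq)
  if (horizon > L %/% 2)
    stop("horizon ", horizon, " exceeds half the sequence length ", L)
  mid <- L %/% 2
  past <- block_strings(data, (mid - horizon + 1L):mid)
  fut <- block_strings(data, (mid + 1L):(mid + horizon))
  pl <- sort(unique(past)); fl <- sort(unique(fut))
  cnt <- table(factor(past, levels = pl), factor(fut, levels = fl))
  counts <- matrix(as.numeric(cnt), length(pl), length(fl),
                   dimnames = list(c(pl), c(fl)))
  counts <- rbind(cbind(counts, `<omega>` = 0), `<omega>` = 0)
  structure(list(counts = counts, horizon = horizon, alphabet = data$alphabet),
            class = "block_count_table")
}

block_strings <- function(data, cols) {
  m <- matrix(data$alphabet[data$seq[, cols, drop = FALSE]], nrow = nrow(data$seq))
  do.call(paste, c(split(m, col(m)), sep = " "))
}

#' Smooth a block count table with the omega pseudo-sequence
#'
#' Adds pseudo-count `gamma` to every `(omega, future)`, `(past, omega)` and
#' `(omega, omega)` cell and normalizes to a [joint_table()]. Held-out items
#' whose past or future block was never observed in training are later scored
#' through these omega cells, keeping the variational bounds finite.
#'
#' @param table a [count_blocks()] result.
#' @param gamma pseudo-count, > 0.
#' @return A [joint_table()] including the omega row and column.
#' @export
smooth_counts <- function(table, gamma) {
  stopifnot(inherits(table, "block_count_table"))
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  cnt <- table$counts
  P <- nrow(cnt); Fc <- ncol(cnt)
  cnt[P, ] <- cnt[P, ] + gamma        # (omega, future) incl. (omega, omega)
  cnt[-P, Fc] <- cnt[-P, Fc] + gamma  # (past, omega)
  joint_table(cnt, normalize = TRUE)
}

#' Optimal Causal Filtering fit
#'
#' The count-based baseline estimator of predictive rate-distortion: counts
#' of (past block, future block) pairs are smoothed with the omega
#' pseudo-sequence and compressed with the information-bottleneck
#' Blahut-Arimoto iteration ([ib_blahut_arimoto()]). Held-out performance is
#' measured with [ocf_evaluate()], which maps unseen blocks to omega.
#'
#' @param train a [trajectory_set()] of training sequences.
#' @param horizon block length M.
#' @param lambda trade-off weight, > 0.
#' @param gamma pseudo-count for smoothing (default 0.001; results are
#'   insensitive over roughly 1e-4..1).
#' @param K codewords; default `min(#distinct observed pasts + 1, 256)`.
#'   Guarded at 1e5 (the count-based codebook is infeasible beyond that).
#' @param restarts,tol,max_iter,seed passed to [ib_blahut_arimoto()].
#' @return An object of class `ocf`: the fitted codebook plus the training
#'   marginal over codewords and the block label maps.
#' @export
ocf <- function(train, horizon, lambda, gamma = 0.001, K = NULL,
                restarts = 10, tol = 1e-10, max_iter = 5000, seed = 1) {
  tab <- count_blocks(train, horizon)
  joint <- smooth_counts(tab, gamma)
  if (is.null(K)) K <- min(nrow(joint), 256L)
  if (K > 1e5)
    stop("K = ", K, " codewords: count-based codebooks beyond 1e5 are infeasible")
  fit <- ib_blahut_arimoto(joint, lambda = lambda, K = K, tol = tol,
                           max_iter = max_iter, restarts = restarts, seed = seed)
  # marginal of Z on the training set: encoder rows weighted by the
  # (smoothed) training past frequencies
  px <- rowSums(unclass(joint))
  s_z <- as.vector(crossprod(fit$encoder, px))
  structure(list(codebook = fit, joint = joint, horizon = horizon,
                 lambda = lambda, gamma = gamma, K = K,
                 past_labels = rownames(joint), future_labels = colnames(joint),
                 train_marginal = s_z / sum(s_z),
                 future_marginal = colSums(unclass(joint)),
                 alphabet = train$alphabet),
            class = "ocf")
}

#' @export
print.ocf <- function(x, ...) {
  cat("OCF fit: M =", x$horizon, ", lambda =", format(x$lambda, digits = 4),
      ",", length(x$past_labels) - 1L, "observed past block(s), K =", x$K, "\n")
  print(x$codebook$point)
  invisible(x)
}

#' Held-out evaluation of an OCF codebook
#'
#' For each test item the past block is encoded (unseen pasts map to omega);
#' the rate estimate is the mean Kullback-Leibler divergence between the
#' item's encoder row and the training marginal over codewords, and the loss
#' estimate is the mean expected negative log-probability of the future block
#' under the decoder (unseen futures scored through the omega column). Both
#' are variational upper bounds up to sampling error. Predictiveness is the
#' cross-entropy of the future blocks under the training block marginal minus
#' the loss.
#'
#' @param fit an [ocf()] object.
#' @param test a [trajectory_set()] of held-out sequences.
#' @return An object of class `ocf_report`: a [prd_point()] row with
#'   standard errors plus counts `n_omega_past`, `n_omega_future`, `n_test`.
#' @export
ocf_evaluate <- function(fit, test) {
  M <- fit$horizon
  L <- ncol(test$seq)
  stopifnot(M <= L %/% 2)
  mid <- L %/% 2
  past <- block_strings(test, (mid - M + 1L):mid)
  fut <- block_strings(test, (mid + 1L):(mid + M))
  pi_idx <- match(past, fit$past_labels)
  fi_idx <- match(fut, fit$future_labels)
  omega_p <- length(fit$past_labels)
  omega_f <- length(fit$future_labels)
  n_op <- sum(is.na(pi_idx)); n_of <- sum(is.na(fi_idx))
  pi_idx[is.na(pi_idx)] <- omega_p
  fi_idx[is.na(fi_idx)] <- omega_f

  enc <- fit$codebook$encoder
  s_z <- fit$train_marginal
  E <- enc[pi_idx, , drop = FALSE]
  lr <- log(pmax(E, 1e-300)) - rep(log(pmax(s_z, 1e-300)), each = nrow(E))
  rate_i <- rowSums(ifelse(E > 0, E * lr, 0))
  ld <- log(pmax(fit$codebook$decoder, 1e-300))    # K x Y
  loss_i <- -rowSums(E * t(ld[, fi_idx, drop = FALSE]))
  ce_i <- -log(pmax(fit$future_marginal[fi_idx], 1e-300))
  d_i <- ce_i - loss_i
  n <- length(rate_i)
  pt <- prd_point(fit$lambda,
                  rate = mean(rate_i), loss = mean(loss_i),
                  predictiveness = mean(d_i),
                  se_rate = stats::sd(rate_i) / sqrt(n),
                  se_loss = stats::sd(loss_i) / sqrt(n),
                  se_predictiveness = stats::sd(d_i) / sqrt(n),
                  converged = fit$codebook$converged)
  structure(list(point = pt, n_omega_past = n_op, n_omega_future = n_of,
                 n_test = n), class = "ocf_report")
}

#' @export
print.ocf_report <- function(x, ...) {
  print(x$point)
  cat(x$n_test, "test item(s);", x$n_omega_past, "unseen past(s),",
      x$n_omega_future, "unseen future(s) mapped to omega\n")
  invisible(x)
}
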