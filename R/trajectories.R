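#' Trajectory sets
#'
#' A `trajectory_set` is an ordered collection of equal-length symbol
#' sequences over a common alphabet, stored as an integer matrix (one row per
#' sequence, symbols coded 1..|alphabet|). For rate-distortion estimation a
#' sequence of length `2M` is read as a past block (columns 1..M) followed by
#' a future block (columns M+1..2M).
#'
#' @param seq integer matrix of symbol indices, or character matrix of
#'   symbols.
#' @param alphabet character vector of symbols.
#' @param split optional tag, e.g. `"train"`, `"val"`, `"test"`.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(seq, alphabet, split = NA_character_) {
  alphabet <- as.character(alphabet)
  if (is.character(seq)) {
    idx <- match(seq, alphabet)
    if (anyNA(idx)) stop("symbol(s) outside the alphabet: ",
                         paste(utils::head(unique(seq[is.na(idx)]), 5), collapse = ", "))
    seq <- matrix(idx, nrow = nrow(seq))
  }
  seq <- as.matrix(seq)
  storage.mode(seq) <- "integer"
  if (length(seq) && (min(seq) < 1L || max(seq) > length(alphabet)))
    stop("symbol index outside the alphabet")
  structure(list(seq = seq, alphabet = alphabet, split = split),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set: ", nrow(x$seq), " sequence(s) of length ", ncol(x$seq),
      ", alphabet {", paste(x$alphabet, collapse = ", "), "}",
      if (!is.na(x$split)) paste0(", split=", x$split), "\n", sep = "")
  invisible(x)
}

#' @export
dim.trajectory_set <- function(x) dim(x$seq)

#' Subset a trajectory set by sequence index
#' @param x a `trajectory_set`.
#' @param i row (sequence) indices.
#' @param ... ignored.
#' @export
`[.trajectory_set` <- function(x, i, ...) {
  trajectory_set(x$seq[i, , drop = FALSE], x$alphabet, x$split)
}

#' Simulate trajectories from a unifilar machine
#'
#' Each sequence starts in a state drawn from the stationary distribution and
#' then alternates emission and (deterministic) state transition, so every
#' time-window of the sampled sequences is distributed according to the
#' stationary process law.
#'
#' @param object a [prd_machine()].
#' @param nsim number of sequences.
#' @param seed integer seed; identical `(machine, nsim, length, seed)`
#'   reproduce identical output.
#' @param length sequence length (use `2 * M` for past/future blocks).
#' @param split optional split tag stored on the result.
#' @param ... ignored.
#' @return A [trajectory_set()].
#' @examples
#' ts <- simulate(build_machine("even"), nsim = 5, seed = 1, length = 30)
#' @export
simulate.prd_machine <- function(object, nsim = 1, seed = NULL, length = 30,
                                 split = NA_character_, ...) {
  stopifnot(nsim >= 1, length >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  S <- nrow(object$emit); A <- ncol(object$emit)
  pi <- stationary_distribution(object)
  state <- sample.int(S, nsim, replace = TRUE, prob = pi)
  out <- matrix(0L, nsim, length)
  # cumulative emission rows for inverse-CDF sampling, vectorized over sequences
  cum <- t(apply(object$emit, 1, cumsum))
  if (S == 1L) cum <- matrix(cum, nrow = 1)
  for (t in seq_len(length)) {
    u <- stats::runif(nsim)
    # symbol = first index where cumsum >= u
    sym <- rep(1L, nsim)
    if (A > 1L) {
      cu <- cum[state, , drop = FALSE]
      sym <- 1L + as.integer(rowSums(cu < u))
      sym[sym > A] <- A
    }
    out[, t] <- sym
    state <- object$trans[cbind(state, sym)]
  }
  trajectory_set(out, object$alphabet, split)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Sample the Copy3 process
#'
#' The past block is iid uniform over three symbols and the future block is
#' its mirror image: the symbol at future position `+i` equals the symbol at
#' past position `-i`. The number of distinct pasts (hence causal states at
#' this horizon) is `3^horizon`.
#'
#' @param n number of sequences.
#' @param horizon block length M; sequences have length `2 * horizon`.
#' @param seed integer seed.
#' @param split optional split tag.
#' @return A [trajectory_set()] over alphabet `{"1","2","3"}`.
#' @export
sample_copy3 <- function(n, horizon = 15, seed = NULL, split = NA_character_) {
  stopifnot(n >= 1, horizon >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  past <- matrix(sample.int(3L, n * horizon, replace = TRUE), n, horizon)
  future <- past[, rev(seq_len(horizon)), drop = FALSE]
  trajectory_set(cbind(past, future), c("1", "2", "3"), split)
}

#' Read / write trajectory files
#'
#' One sequence per line, single-space-separated symbol tokens, UTF-8,
#' newline-terminated. All lines must contain the same number of tokens.
#'
#' @param path file path.
#' @param alphabet optional fixed alphabet for reading. When supplied
#'   together with `vocab`, unknown tokens follow the vocabulary replacement
#'   policy; without it, unknown tokens are an error. When omitted, the
#'   alphabet is inferred from the file (sorted unique tokens).
#' @param vocab optional [vocabulary()] applied to out-of-alphabet tokens.
#' @param split optional split tag for the result.
#' @return `read_trajectories`: a [trajectory_set()].
#' @export
read_trajectories <- function(path, alphabet = NULL, vocab = NULL,
                              split = NA_character_) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty trajectory file: ", path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  lens <- lengths(toks)
  if (any(lens != lens[1]))
    stop("ragged trajectory file: line ", which(lens != lens[1])[1],
         " has ", lens[lens != lens[1]][1], " tokens, expected ", lens[1])
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(flat))
  } else if (!is.null(vocab)) {
    flat <- replace_oov(flat, vocab)
  }
  idx <- match(flat, alphabet)
  if (anyNA(idx))
    stop("token(s) outside the supplied alphabet: ",
         paste(utils::head(unique(flat[is.na(idx)]), 5), collapse = ", "))
  trajectory_set(matrix(idx, nrow = length(lines), byrow = TRUE), alphabet, split)
}

#' @rdname read_trajectories
#' @param data a [trajectory_set()] to write.
#' @return `write_trajectories`: `path`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  stopifnot(inherits(data, "trajectory_set"))
  syms <- matrix(data$alphabet[data$seq], nrow = nrow(data$seq))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(apply(syms, 1, paste, collapse = " "), con, useBytes = TRUE)
  invisible(path)
}

#' Split a trajectory set into train/val/test partitions
#'
#' @param data a [trajectory_set()].
#' @param n_val,n_test sizes of the validation and test partitions, taken
#'   from the end; the remainder is the training partition.
#' @return Named list of three `trajectory_set`s.
#' @export
split_trajectories <- function(data, n_val, n_test) {
  n <- nrow(data$seq)
  stopifnot(n_val + n_test < n)
  i_test <- seq.int(n - n_test + 1L, n)
  i_val <- seq.int(n - n_test - n_val + 1L, n - n_test)
  i_train <- seq_len(n - n_test - n_val)
  list(train = trajectory_set(data$seq[i_train, , drop = FALSE], data$alphabet, "train"),
       val = trajectory_set(data$seq[i_val, , drop = FALSE], data$alphabet, "val"),
       test = trajectory_set(data$seq[i_test, , drop = FALSE], data$alphabet, "test"))
}
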