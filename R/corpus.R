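#' Frequency-ranked vocabulary with a size cap
#'
#' Token ids are dense `0..V-1`, assigned by decreasing corpus frequency
#' (ties broken alphabetically), so the most frequent token gets id 0. Tokens
#' outside the vocabulary are replaced: by a parallel part-of-speech tag when
#' one is supplied, otherwise by the single unknown symbol `<unk>`.
#'
#' @param tokens character vector of corpus tokens.
#' @param cap maximum number of distinct token types kept (>= 2).
#' @return An object of class `vocabulary`: fields `tokens` (rank order),
#'   `id` (named integer vector, 0-based), `freq`, `unk`.
#' @export
vocabulary <- function(tokens, cap = 1e4) {
  if (!length(tokens)) stop("empty corpus")
  if (cap < 2) stop("vocab_cap must be at least 2")
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  kept <- names(tab)[ord][seq_len(min(cap, length(tab)))]
  structure(list(
    tokens = kept,
    id = stats::setNames(seq_along(kept) - 1L, kept),
    freq = stats::setNames(as.integer(tab)[ord][seq_along(kept)], kept),
    unk = "<unk>"
  ), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("vocabulary:", length(x$tokens), "types, unk =", x$unk, "\n")
  invisible(x)
}

#' Apply the out-of-vocabulary replacement policy
#'
#' @param tokens character vector.
#' @param vocab a [vocabulary()].
#' @param tags optional parallel character vector of part-of-speech tags used
#'   as replacements for out-of-vocabulary tokens.
#' @return Character vector with OOV tokens replaced.
#' @export
replace_oov <- function(tokens, vocab, tags = NULL) {
  oov <- !(tokens %in% vocab$tokens)
  if (any(oov)) {
    if (!is.null(tags)) {
      stopifnot(length(tags) == length(tokens))
      tokens[oov] <- paste0("<", tags[oov], ">")
    } else {
      tokens[oov] <- vocab$unk
    }
  }
  tokens
}

#' Load a tokenized corpus as padded past/future windows
#'
#' Reads a whitespace-tokenized corpus (one sentence or segment per line),
#' builds a frequency-ranked [vocabulary()] capped at `vocab_cap`, replaces
#' out-of-vocabulary tokens (by the tag column of `tag_path` when given, else
#' by `<unk>`), and emits one window of length `2 * horizon` per line:
#' sentences are left-padded with the `<pad>` symbol or truncated to fit.
#' The pad symbol index is stored in attribute `pad` of the result and is
#' intended to be masked out of prediction losses.
#'
#' @param path corpus file.
#' @param vocab_cap vocabulary size cap (default `1e4`).
#' @param horizon block length M.
#' @param tag_path optional parallel file of part-of-speech tags with the
#'   same tokenization.
#' @return List with elements `data` (a [trajectory_set()]) and `vocab`.
#' @export
load_corpus <- function(path, vocab_cap = 1e4, horizon = 15, tag_path = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty corpus")
  toks <- strsplit(trimws(lines), "\\s+")
  tags <- NULL
  if (!is.null(tag_path)) {
    tlines <- readLines(tag_path, warn = FALSE, encoding = "UTF-8")
    tlines <- tlines[nzchar(trimws(tlines))]
    tags <- strsplit(trimws(tlines), "\\s+")
    if (!identical(lengths(tags), lengths(toks)))
      stop("tag file does not align with the corpus tokenization")
  }
  vocab <- vocabulary(unlist(toks, use.names = FALSE), cap = vocab_cap)
  L <- 2L * horizon
  pad <- "<pad>"
  win <- vapply(seq_along(toks), function(i) {
    tk <- replace_oov(toks[[i]], vocab, if (is.null(tags)) NULL else tags[[i]])
    if (length(tk) >= L) tk[seq_len(L)] else c(rep(pad, L - length(tk)), tk)
  }, character(L))
  win <- t(win)
  alphabet <- c(vocab$tokens,
                setdiff(sort(unique(as.vector(win))), vocab$tokens))
  ts <- trajectory_set(matrix(match(win, alphabet), nrow = nrow(win)), alphabet)
  attr(ts, "pad") <- match(pad, alphabet)
  list(data = ts, vocab = vocab)
}
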