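#' Unifilar hidden Markov machines (epsilon-machine presentations)
#'
#' A `prd_machine` is a unifilar (deterministic-transition) hidden Markov
#' model: each state carries an emission distribution over a finite alphabet,
#' and the next state is a deterministic function of (state, emitted symbol).
#' When the states are the causal states of the process, the machine is its
#' epsilon-machine and the entropy of the stationary state distribution is
#' the statistical complexity.
#'
#' @param states character vector of state labels.
#' @param alphabet character vector of symbols.
#' @param emit numeric matrix, `length(states)` x `length(alphabet)`; row
#'   `s` is the emission distribution of state `s` (rows sum to 1).
#' @param trans integer matrix of the same shape; `trans[s, a]` is the index
#'   of the successor state when state `s` emits symbol `a`. Entries where
#'   `emit[s, a] == 0` are ignored (may be `NA`).
#' @param name optional display name.
#'
#' @return An object of class `prd_machine`.
#' @seealso [build_machine()], [stationary_distribution()],
#'   [statistical_complexity()], [simulate.prd_machine()]
#' @export
prd_machine <- function(states, alphabet, emit, trans, name = "custom") {
  states <- as.character(states)
  alphabet <- as.character(alphabet)
  emit <- as.matrix(emit)
  trans <- as.matrix(trans)
  storage.mode(trans) <- "integer"
  dimnames(emit) <- list(states, alphabet)
  dimnames(trans) <- list(states, alphabet)
  m <- structure(
    list(states = states, alphabet = alphabet, emit = emit, trans = trans,
         name = name),
    class = "prd_machine"
  )
  validate_machine(m)
  m
}

validate_machine <- function(m) {
  S <- length(m$states); A <- length(m$alphabet)
  if (S < 1L || A < 1L) stop("machine needs at least one state and one symbol")
  if (!identical(dim(m$emit), c(S, A)) || !identical(dim(m$trans), c(S, A)))
    stop("emission/transition matrices must be |states| x |alphabet|")
  if (any(m$emit < 0))
    stop("negative emission probability in row(s): ",
         paste(m$states[apply(m$emit < 0, 1, any)], collapse = ", "))
  rs <- rowSums(m$emit)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad))
    stop("emission row does not sum to 1 for state(s): ",
         paste(m$states[bad], collapse = ", "))
  live <- m$emit > 0
  tr <- m$trans[live]
  if (any(is.na(tr)) || any(tr < 1L) || any(tr > S))
    stop("transition target missing or out of range on a positive-probability edge")
  # the recurrent states (members of terminal communicating classes) must
  # form a single irreducible class
  reach <- lapply(seq_len(S), function(s) reachable_states(m, s))
  recurrent <- which(vapply(seq_len(S), function(s)
    all(vapply(reach[[s]], function(t) s %in% reach[[t]], TRUE)), TRUE))
  for (s in recurrent) {
    missing <- setdiff(recurrent, reach[[s]])
    if (length(missing))
      stop("machine is reducible: state(s) ",
           paste(m$states[missing], collapse = ", "),
           " unreachable from ", m$states[s])
  }
  invisible(m)
}

reachable_states <- function(m, from) {
  seen <- logical(length(m$states)); seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(stats::na.omit(as.integer(m$trans[frontier, , drop = FALSE][m$emit[frontier, , drop = FALSE] > 0])))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Build a benchmark machine by name
#'
#' Built-in machines:
#' \describe{
#'   \item{`even`}{Even Process: fair coin flips conditioned on every maximal
#'     block of consecutive 1s having even length. States E, O; E emits 0
#'     (prob 1/2, stay E) or 1 (prob 1/2, to O); O emits 1 surely, back to E.
#'     Statistical complexity H(2/3, 1/3) = 0.6365 nats.}
#'   \item{`rip`}{Random Insertion Process, three causal states. A emits 0
#'     (1/2, to B) or 1 (1/2, to C); B emits either symbol (1/2 each, to C);
#'     C emits 1 surely, to A. Stationary distribution (2/5, 1/5, 2/5).}
#'   \item{`iid_coin`}{A single-state fair coin (memoryless).}
#' }
#' A name of the form `custom:<path>` loads a machine spec file, see
#' [read_machine()].
#'
#' @param name one of `"even"`, `"rip"`, `"iid_coin"`, or `"custom:<path>"`.
#' @return A [prd_machine()].
#' @examples
#' m <- build_machine("even")
#' stationary_distribution(m)           # (2/3, 1/3)
#' statistical_complexity(m)            # 0.6365 nats
#' @export
build_machine <- function(name) {
  if (startsWith(name, "custom:"))
    return(read_machine(sub("^custom:", "", name)))
  switch(name,
    even = prd_machine(
      states = c("E", "O"), alphabet = c("0", "1"),
      emit  = rbind(c(0.5, 0.5), c(0, 1)),
      trans = rbind(c(1L, 2L), c(NA, 1L)),
      name = "even"),
    rip = prd_machine(
      states = c("A", "B", "C"), alphabet = c("0", "1"),
      emit  = rbind(c(0.5, 0.5), c(0.5, 0.5), c(0, 1)),
      trans = rbind(c(2L, 3L), c(3L, 3L), c(NA, 1L)),
      name = "rip"),
    iid_coin = prd_machine(
      states = "S", alphabet = c("0", "1"),
      emit  = matrix(c(0.5, 0.5), 1), trans = matrix(c(1L, 1L), 1),
      name = "iid_coin"),
    stop("unknown machine name: ", name)
  )
}

#' Stationary distribution of a machine
#'
#' Solves the balance equations pi = pi T, where `T[s, s']` is the total
#' probability of moving from state `s` to `s'` in one emission.
#'
#' @param machine a [prd_machine()].
#' @return Named numeric vector summing to 1.
#' @export
stationary_distribution <- function(machine) {
  S <- length(machine$states)
  if (S == 1L) return(stats::setNames(1, machine$states))
  Tm <- matrix(0, S, S)
  for (s in seq_len(S)) for (a in seq_along(machine$alphabet)) {
    p <- machine$emit[s, a]
    if (p > 0) Tm[s, machine$trans[s, a]] <- Tm[s, machine$trans[s, a]] + p
  }
  # solve pi (T - I) = 0 with sum(pi) = 1
  Aeq <- rbind(t(Tm) - diag(S), rep(1, S))
  b <- c(rep(0, S), 1)
  pi <- qr.solve(Aeq, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  stats::setNames(pi / sum(pi), machine$states)
}

#' Statistical complexity (nats)
#'
#' Shannon entropy, in nats, of the stationary distribution over machine
#' states. For an epsilon-machine this is the statistical complexity of the
#' process: the memory cost of optimal prediction.
#'
#' @inheritParams stationary_distribution
#' @return Entropy in nats.
#' @export
statistical_complexity <- function(machine) {
  p <- stationary_distribution(machine)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @export
print.prd_machine <- function(x, ...) {
  cat("Unifilar HMM '", x$name, "': ", length(x$states), " state(s), alphabet {",
      paste(x$alphabet, collapse = ", "), "}\n", sep = "")
  pi <- stationary_distribution(x)
  cat("stationary:", paste(sprintf("%s=%.4g", names(pi), pi), collapse = ", "), "\n")
  cat("statistical complexity:", format(statistical_complexity(x), digits = 4), "nats\n")
  invisible(x)
}

#' Read a machine spec file
#'
#' Plain-text `key: value` format. Required keys: `states` (space-separated
#' labels), `alphabet` (space-separated symbols), then one line per state of
#' the form `state <label>: <sym>-><prob>-><target> ...` listing, for each
#' symbol with positive probability, the emission probability and successor
#' state. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return A validated [prd_machine()].
#' @examples
#' f <- tempfile()
#' writeLines(c("states: E O", "alphabet: 0 1",
#'              "state E: 0->0.5->E 1->0.5->O", "state O: 1->1->E"), f)
#' build_machine(paste0("custom:", f))
#' @export
read_machine <- function(path) {
  if (!file.exists(path)) stop("machine spec file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  getval <- function(key) {
    hit <- grep(paste0("^", key, "\\s*:"), lines, value = TRUE)
    if (length(hit) != 1) stop("machine spec needs exactly one '", key, ":' line")
    strsplit(trimws(sub("^[^:]*:", "", hit)), "\\s+")[[1]]
  }
  states <- getval("states")
  alphabet <- getval("alphabet")
  S <- length(states); A <- length(alphabet)
  emit <- matrix(0, S, A); trans <- matrix(NA_integer_, S, A)
  for (ln in grep("^state\\s", lines, value = TRUE)) {
    head <- sub("^state\\s+([^:]+):.*$", "\\1", ln)
    s <- match(trimws(head), states)
    if (is.na(s)) stop("machine spec: unknown state label '", head, "'")
    for (tok in strsplit(trimws(sub("^[^:]*:", "", ln)), "\\s+")[[1]]) {
      parts <- strsplit(tok, "->", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("machine spec: bad edge token '", tok, "'")
      a <- match(parts[1], alphabet)
      if (is.na(a)) stop("machine spec: unknown symbol '", parts[1], "'")
      emit[s, a] <- as.numeric(parts[2])
      trans[s, a] <- match(parts[3], states)
      if (is.na(trans[s, a])) stop("machine spec: unknown target state '", parts[3], "'")
    }
  }
  prd_machine(states, alphabet, emit, trans, name = basename(path))
}

#' Write a machine spec file
#'
#' Inverse of [read_machine()].
#' @param machine a [prd_machine()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_machine <- function(machine, path) {
  out <- c(paste("states:", paste(machine$states, collapse = " ")),
           paste("alphabet:", paste(machine$alphabet, collapse = " ")))
  for (s in seq_along(machine$states)) {
    toks <- character(0)
    for (a in seq_along(machine$alphabet)) {
      if (machine$emit[s, a] > 0)
        toks <- c(toks, paste0(machine$alphabet[a], "->",
                               format(machine$emit[s, a], digits = 17), "->",
                               machine$states[machine$trans[s, a]]))
    }
    out <- c(out, paste0("state ", machine$states[s], ": ",
                         paste(toks, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
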