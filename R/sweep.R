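#' Sweep the neural estimator across trade-off weights
#'
#' Trains and evaluates one [nprd()] bundle per lambda, collecting the
#' held-out points into a run table ready for [pareto_frontier()] and
#' [fit_ansatz()]. Lambdas are sampled uniformly in (0, 1) unless supplied.
#' With `out_dir` set, each completed run is written to
#' `run-<id>.json` and re-invoking the sweep skips completed runs
#' (resumability); each file embeds the configuration that produced it.
#' A failed run is logged and skipped, not fatal.
#'
#' @param process name for [build_machine()], or a list with elements
#'   `train`, `val`, `test` ([trajectory_set()]s) for user data.
#' @param n_runs number of (lambda, seed) runs.
#' @param lambda optional vector of lambdas (length `n_runs`).
#' @param n_train,n_val,n_test sequence counts simulated per run when
#'   `process` is a machine name.
#' @param horizon block length M; simulated sequences have length
#'   `2 * horizon`.
#' @param config an [nprd_config()]; the default uses a small network
#'   (hidden 16, code dimension 4, batch 256, Adam step 3e-3, at most 10
#'   passes, patience 2) sized for single-CPU sweeps.
#' @param seed master seed; run `r` trains with seed `seed + r` on data
#'   simulated with seeds derived from `seed`.
#' @param out_dir optional directory for resumable per-run JSON records.
#' @param verbose print progress.
#' @return data.frame of class `prd_runs`: one row per completed run with
#'   lambda, rate, loss, predictiveness, objective, standard errors, run id
#'   and training metadata.
#' @export
prd_sweep <- function(process = "even", n_runs = 12, lambda = NULL,
                      n_train = 5e4, n_val = 1500, n_test = 3000,
                      horizon = 15,
                      config = nprd_config(hidden = 16, code_dim = 4,
                                           batch_size = 256, lr = 3e-3,
                                           max_epochs = 10, patience = 2),
                      seed = 1, out_dir = NULL, verbose = FALSE) {
  if (is.null(lambda)) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    lambda <- stats::runif(n_runs)
    restore_rng(old)
  }
  stopifnot(length(lambda) == n_runs, all(lambda > 0 & lambda < 1))
  if (is.character(process)) {
    m <- build_machine(process)
    train <- simulate(m, nsim = n_train, seed = seed * 1000L + 1L,
                      length = 2 * horizon, split = "train")
    val <- simulate(m, nsim = n_val, seed = seed * 1000L + 2L,
                    length = 2 * horizon, split = "val")
    test <- simulate(m, nsim = n_test, seed = seed * 1000L + 3L,
                     length = 2 * horizon, split = "test")
  } else {
    train <- process$train; val <- process$val; test <- process$test
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (r in seq_len(n_runs)) {
    run_id <- sprintf("run-%03d", r)
    f <- if (!is.null(out_dir)) file.path(out_dir, paste0(run_id, ".json")) else NULL
    if (!is.null(f) && file.exists(f)) {
      rows[[r]] <- as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE)$point)
      next
    }
    res <- tryCatch({
      b <- nprd(train, val, lambda = lambda[r], config = config,
                seed = seed + r, verbose = FALSE)
      rep <- nprd_evaluate(b, test, seed = seed + 10000L + r)
      pt <- rep$point
      pt$run <- run_id; pt$seed <- seed + r; pt$passes <- nrow(b$log)
      pt$eta_ce <- rep$eta_ce
      if (!is.null(f))
        jsonlite::write_json(list(point = pt, config = unclass(config),
                                  lambda = lambda[r], seed = seed + r),
                             f, auto_unbox = TRUE, digits = NA)
      if (verbose)
        cat(sprintf("%s: lambda=%.3f rate=%.3f pred=%.3f (%d passes)\n",
                    run_id, lambda[r], pt$rate, pt$predictiveness, pt$passes))
      pt
    }, error = function(e) {
      warning("run ", run_id, " failed: ", conditionMessage(e))
      NULL
    })
    rows[[r]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(out) <- c("prd_runs", "data.frame")
  out
}

#' Write deterministic test/demo fixtures
#'
#' Writes small plain-text fixtures: 2000 Even Process and 2000 Random
#' Insertion Process sequences (length 30, seed 0), 500 Copy3 pairs
#' (horizon 5), and a 200-line synthetic toy-language corpus generated from
#' a bundled 6-state, 12-symbol unifilar machine. Regeneration is
#' byte-identical.
#'
#' @param outdir writable directory.
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(even = file.path(outdir, "even-2000x30.txt"),
             rip = file.path(outdir, "rip-2000x30.txt"),
             copy3 = file.path(outdir, "copy3-500xM5.txt"),
             corpus = file.path(outdir, "toy-corpus-200.txt"),
             machine = file.path(outdir, "toy-machine.txt"))
  write_trajectories(simulate(build_machine("even"), nsim = 2000, seed = 0,
                              length = 30), paths["even"])
  write_trajectories(simulate(build_machine("rip"), nsim = 2000, seed = 0,
                              length = 30), paths["rip"])
  write_trajectories(sample_copy3(500, horizon = 5, seed = 0), paths["copy3"])
  m <- toy_language_machine()
  write_machine(m, paths["machine"])
  write_trajectories(simulate(m, nsim = 200, seed = 0, length = 30),
                     paths["corpus"])
  invisible(paths)
}

#' A small synthetic "toy language" machine
#'
#' Six states in a cycle, each emitting one of its own pair of word-like
#' symbols (12 in total): one symbol advances one state, the other skips a
#' state. Used to generate corpus fixtures with known structure.
#'
#' @return A [prd_machine()].
#' @export
toy_language_machine <- function() {
  S <- 6
  alphabet <- sprintf("w%02d", 1:12)
  emit <- matrix(0, S, 12)
  trans <- matrix(NA_integer_, S, 12)
  for (s in 1:S) {
    a1 <- 2 * s - 1; a2 <- 2 * s
    emit[s, a1] <- 0.5; emit[s, a2] <- 0.5
    trans[s, a1] <- s %% S + 1L
    trans[s, a2] <- (s + 1L) %% S + 1L
  }
  prd_machine(sprintf("s%d", 1:S), alphabet, emit, trans,
              name = "toy_language")
}
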