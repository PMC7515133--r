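# Session-level cache so expensive fitted objects are built once and shared
# across test files.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

# Small Even-process NPRD bundle used by several tests: modest data and
# network, a couple of passes; enough to be meaningfully trained.
even_bundle <- function() {
  cached("even_bundle", {
    m <- build_machine("even")
    tr <- simulate(m, nsim = 20000, seed = 101, length = 30)
    va <- simulate(m, nsim = 800, seed = 102, length = 30)
    cfg <- nprd_config(hidden = 16, code_dim = 4, batch_size = 256,
                       lr = 3e-3, max_epochs = 6, patience = 2)
    nprd(tr, va, lambda = 0.3, config = cfg, seed = 7)
  })
}

even_test_set <- function() {
  cached("even_test_set",
         simulate(build_machine("even"), nsim = 2000, seed = 103, length = 30))
}

# Random small joint tables for IB oracle comparisons.
random_joint <- function(nx, ny, seed) {
  old <- globalenv()$.Random.seed
  on.exit(nprd:::restore_rng(old))
  set.seed(seed)
  p <- matrix(stats::rexp(nx * ny), nx, ny)
  joint_table(p / sum(p))
}

# Exhaustive search over deterministic encoders with exact marginal/decoder:
# the independent oracle for the Blahut-Arimoto objective. Returns the best
# objective for each lambda (the per-assignment conditional entropy and
# codeword entropy are lambda-independent and computed once).
best_deterministic_objective <- function(joint, lambdas, K = nrow(joint)) {
  p <- unclass(joint)
  px <- rowSums(p)
  nx <- nrow(p)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(K)), nx)))
  hyz <- numeric(nrow(assignments))
  hq <- numeric(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    rows <- rowsum(p, a)                     # p(z, y)
    qz <- rowSums(rows)
    pos <- rows > 0
    hyz[i] <- -sum(rows[pos] * (log(rows[pos]) - log(qz[row(rows)[pos]])))
    hq[i] <- entropy_nats(qz)                # I[X;Z] = H[Z] for det. encoder
  }
  vapply(lambdas, function(l) min(hyz + l * hq), 0)
}

# ---- shared objects for the acceptance-level checks ----

# Analytic Even-Process curve at the evaluation horizon.
acceptance_curve <- function() {
  cached("acceptance_curve",
         analytic_prd_curve(build_machine("even"), 15,
                            lambda_grid = c(0.02, 0.05, 0.1, 0.15, 0.2, 0.3,
                                            0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
                            seed = 2))
}

# Scaled-down Even sweep: 12 runs on 5e4 training sequences, small networks.
acceptance_sweep <- function() {
  cached("acceptance_sweep", prd_sweep("even", n_runs = 12, seed = 1))
}

# RIP bundle trained at lambda = 0.25 plus its code-space interpretation.
acceptance_rip <- function() {
  cached("acceptance_rip", {
    m <- build_machine("rip")
    cfg <- nprd_config(hidden = 16, code_dim = 4, batch_size = 256,
                       lr = 2e-3, max_epochs = 24, patience = 3)
    tr <- simulate(m, nsim = 5e4, seed = 1001, length = 30)
    va <- simulate(m, nsim = 1500, seed = 1002, length = 30)
    te <- simulate(m, nsim = 5000, seed = 1003, length = 30)
    b <- nprd(tr, va, lambda = 0.25, config = cfg, seed = 21)
    report <- nprd_evaluate(b, te, seed = 31)
    pasts <- te$seq[, 1:15]
    z <- sample_code(encode_past(b, pasts), seed = 41)
    pr <- pca_codes(z)
    cl <- cluster_codes(pr, seed = 51)
    cs <- causal_state_of_past(m, pasts)
    pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, 1:2, drop = FALSE]
    for (j in 1:2) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    proj_fn <- function(zz) scale(zz, center = pc$center, scale = FALSE) %*% rot
    valid <- t(vapply(seq_len(nrow(pasts)), function(i) {
      if (is.na(cs[i])) rep(FALSE, 2) else m$emit[cs[i], ] > 0
    }, logical(2)))
    tm <- if (cl$k >= 2)
      transition_map(b, pasts, cl$cluster, cl$centers, proj_fn,
                     keep = !is.na(cs), valid_append = valid, seed = 61)
    else NULL
    curve <- analytic_prd_curve(m, 15,
                                lambda_grid = c(0.05, 0.15, 0.25, 0.4, 0.6, 0.8),
                                seed = 3)
    list(bundle = b, report = report, clusters = cl, causal_states = cs,
         transitions = tm, curve = curve)
  })
}
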