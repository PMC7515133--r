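test_that("high trade-off weights collapse to the zero-rate code", {
  even_j <- causal_future_joint(build_machine("even"), 8, labels = FALSE)
  joints <- list(even_j, random_joint(4, 4, 1), random_joint(5, 3, 2))
  for (j in joints) {
    for (lam in c(1.0, 1.2, 2.0)) {
      fit <- ib_blahut_arimoto(j, lambda = lam, K = 4, seed = 3, restarts = 3)
      expect_lt(fit$point$rate, 1e-8)
      expect_equal(effective_codewords(fit), 1L)
      # zero-rate loss is the marginal target entropy
      expect_equal(fit$point$loss, entropy_nats(colSums(unclass(j))),
                   tolerance = 1e-6)
    }
  }
})

test_that("the low-lambda limit recovers the causal-state code", {
  even <- build_machine("even")
  j <- causal_future_joint(even, 15, labels = FALSE)
  fit <- ib_blahut_arimoto(j, lambda = 0.05, K = 4, seed = 1, restarts = 5)
  expect_equal(fit$point$predictiveness, mutual_information(j), tolerance = 1e-3)
  expect_equal(fit$point$rate, statistical_complexity(even), tolerance = 1e-3)
  expect_true(fit$monotone)
  expect_true(fit$converged)
})

test_that("soft codebooks never lose to exhaustive deterministic encoders", {
  # independent oracle: every deterministic assignment of sources to
  # codewords, with the exact induced marginal and Bayes decoder
  set.seed(77)
  lambdas <- c(0.2, 0.5, 0.8)
  for (s in 1:12) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    j <- random_joint(nx, ny, seed = 100 + s)
    oracle <- best_deterministic_objective(j, lambdas, K = nx)
    for (i in seq_along(lambdas)) {
      fit <- ib_blahut_arimoto(j, lambda = lambdas[i], K = nx, seed = s,
                               restarts = 10)
      expect_lte(fit$point$objective, oracle[i] + 1e-6)
      expect_true(fit$monotone)
    }
  }
})

test_that("every fitted point respects the rate bound on predictiveness", {
  j <- causal_future_joint(build_machine("rip"), 10, labels = FALSE)
  for (lam in c(0.1, 0.3, 0.7, 1.5)) {
    p <- ib_blahut_arimoto(j, lam, K = 5, seed = 2, restarts = 3)$point
    expect_lte(p$predictiveness, p$rate + 1e-8)
    expect_gte(p$rate, 0)
    expect_gte(p$predictiveness, -1e-12)
  }
})

test_that("RIP effective codeword counts switch at the known boundary", {
  j <- causal_future_joint(build_machine("rip"), 15, labels = FALSE)
  f25 <- ib_blahut_arimoto(j, 0.25, K = 3, seed = 2, restarts = 10)
  expect_equal(effective_codewords(f25), 3L)
  f60 <- ib_blahut_arimoto(j, 0.6, K = 3, seed = 2, restarts = 10)
  expect_equal(effective_codewords(f60), 2L)
})

test_that("identity-style joints put the whole curve on the diagonal", {
  j <- joint_table(diag(4) / 4)
  for (lam in c(0.3, 0.7)) {
    p <- ib_blahut_arimoto(j, lam, K = 4, seed = 1, restarts = 5)$point
    expect_equal(p$predictiveness, p$rate, tolerance = 1e-6)
  }
})

test_that("analytic curves are Pareto-consistent and hit both endpoints", {
  even <- build_machine("even")
  curve <- analytic_prd_curve(even, horizon = 10,
                              lambda_grid = c(0.05, 0.2, 0.4, 0.6, 0.8, 1.5),
                              seed = 4)
  expect_true(attr(curve, "pareto_ok"))
  expect_true(all(curve$converged))
  # trivial-code endpoint: zero rate, loss = H of the future block
  top <- curve[curve$lambda == 1.5, ]
  expect_lt(top$rate, 1e-8)
  expect_equal(top$loss, block_entropy(even, 10), tolerance = 1e-6)
  # causal-state endpoint
  bot <- curve[curve$lambda == 0.05, ]
  expect_equal(bot$rate, statistical_complexity(even), tolerance = 1e-3)
  # curve TSV export round-trips
  f <- tempfile(fileext = ".tsv")
  write_curve(curve, f)
  back <- read.delim(f)
  expect_equal(back$rate_nats, curve$rate, tolerance = 1e-12)
})

test_that("curves from the block joint track the causal-state curve", {
  even <- build_machine("even")
  grid <- c(0.1, 0.3, 0.6)
  c1 <- analytic_prd_curve(even, 8, grid, seed = 1)
  j2 <- block_joint_bruteforce(even, 8, labels = FALSE)
  obj2 <- vapply(grid, function(l)
    ib_blahut_arimoto(j2, l, K = 4, seed = 1, restarts = 5)$point$objective, 0)
  # compressing finite past blocks is strictly harder than compressing the
  # causal state, by an amount controlled by the finite-past ambiguity
  # (the all-ones block, probability ~2^(-M/2); measured < 0.09 at M=8)
  expect_true(all(obj2 >= c1$objective - 1e-6))
  expect_true(all(obj2 - c1$objective < 0.12))
})
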