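test_that("Pareto dominance filters and sorts runs", {
  one <- data.frame(rate = 1, predictiveness = 0.5, lambda = 0.3)
  expect_equal(nrow(pareto_frontier(one)), 1)
  two <- data.frame(rate = c(1, 2), predictiveness = c(0.5, 0.4))
  expect_equal(pareto_frontier(two)$rate, 1)    # (2, 0.4) is dominated
  runs <- data.frame(rate = c(0.2, 0.5, 0.4, 1.0),
                     predictiveness = c(0.1, 0.3, 0.35, 0.6))
  fr <- pareto_frontier(runs)
  expect_true(all(diff(fr$rate) > 0))
  expect_true(all(diff(fr$predictiveness) > 0))
  expect_false(any(fr$rate == 0.5))             # dominated by (0.4, 0.35)
  # interpolation: beyond the last point the frontier is flat
  expect_equal(frontier_predictiveness(fr, c(0, 2)), c(0, 0.6))
})

test_that("the ansatz is recovered exactly from noiseless points", {
  lam <- exp(seq(log(0.002), log(0.9), length.out = 40))
  R <- log(1 / lam)^1.7
  P <- 1.13 - 1.7 * nprd:::inc_gamma_upper(1.7, R^(1 / 1.7))
  fit <- fit_ansatz(data.frame(lambda = lam, rate = R, predictiveness = P))
  expect_equal(fit$alpha, 1, tolerance = 1e-6)
  expect_equal(fit$beta, 1.7, tolerance = 1e-6)
  expect_equal(fit$E0, 1.13, tolerance = 1e-6)
  # self-consistency: predictions reproduce the generating points
  pred <- ansatz_predict(fit, lam, "from-lambda")
  expect_equal(pred$rate, R, tolerance = 1e-6)
  expect_equal(pred$predictiveness, P, tolerance = 1e-6)
})

test_that("the ansatz survives observation noise within 10 percent", {
  set.seed(31)
  lam <- exp(runif(120, log(0.002), log(0.9)))
  R <- pmax(log(1 / lam)^1.7 + rnorm(120, sd = 0.05), 1e-4)
  P <- 1.13 - 1.7 * nprd:::inc_gamma_upper(1.7, R^(1 / 1.7)) +
    rnorm(120, sd = 0.05)
  fit <- fit_ansatz(data.frame(lambda = lam, rate = R, predictiveness = P))
  expect_lt(abs(fit$alpha - 1), 0.1)
  expect_lt(abs(fit$beta - 1.7), 0.17)
  expect_lt(abs(fit$E0 - 1.13), 0.113)
})

test_that("ansatz curves have the analytic slope and limits", {
  fit <- structure(list(alpha = 1, beta = 1.7, E0 = 1.13), class = "prd_ansatz")
  h <- 1e-6
  for (r0 in c(0.5, 2, 5)) {
    num <- (ansatz_predict(fit, r0 + h, "from-rate")$predictiveness -
              ansatz_predict(fit, r0 - h, "from-rate")$predictiveness) / (2 * h)
    expect_equal(num, exp(-(r0 / fit$alpha)^(1 / fit$beta)), tolerance = 1e-5)
  }
  # endpoints: P(0) = E0 - alpha*beta*Gamma(beta); P(Inf) = E0
  expect_equal(ansatz_predict(fit, 0, "from-rate")$predictiveness,
               1.13 - 1.7 * gamma(1.7), tolerance = 1e-12)
  expect_equal(ansatz_predict(fit, 1e6, "from-rate")$predictiveness, 1.13,
               tolerance = 1e-9)
  # degenerate spread is rejected
  expect_error(fit_ansatz(data.frame(lambda = rep(0.5, 6), rate = 1:6 / 10,
                                     predictiveness = 1:6 / 20)),
               "degenerate|widen")
})

test_that("PCA projections are deterministic with fixed sign convention", {
  set.seed(8)
  line <- outer(rnorm(50), c(1, 2, -1))      # 1-D subspace in 3-D
  pr <- pca_codes(line)
  expect_lt(var(pr[, 2]), 1e-20)
  perm <- sample(50)
  pr2 <- pca_codes(line[perm, ])
  expect_equal(pr2, pr[perm, ], tolerance = 1e-10)
})

test_that("silhouette-guided clustering finds planted modes", {
  set.seed(9)
  centers <- rbind(c(0, 0), c(6, 0), c(3, 5))
  pts <- centers[rep(1:3, each = 120), ] + matrix(rnorm(720, sd = 0.4), 360, 2)
  cl <- cluster_codes(pts, seed = 2)
  expect_equal(cl$k, 3L)
  expect_equal(length(unique(cl$cluster)), 3L)
  # a single blob yields one cluster
  blob <- matrix(rnorm(400, sd = 0.5), 200, 2)
  expect_equal(cluster_codes(blob, seed = 2)$k, 1L)
})

test_that("causal-state attribution flags ambiguous pasts", {
  even <- build_machine("even")
  # ...0 resolves to state E regardless of start; all-ones is ambiguous
  p <- rbind(c(2, 2, 1), c(2, 2, 2))
  cs <- causal_state_of_past(even, p)
  expect_equal(cs[1], 1L)
  expect_true(is.na(cs[2]))
  # "...0 1" ends in O (odd run in progress)
  expect_equal(causal_state_of_past(even, rbind(c(1, 1, 2)))[1], 2L)
})

test_that("one-cluster transition maps are self-loops", {
  b <- even_bundle()
  te <- even_test_set()
  pasts <- te$seq[1:200, 1:15]
  centers <- matrix(c(0, 0), 1)
  proj_fn <- function(z) z[, 1:2, drop = FALSE] * 0
  tm <- transition_map(b, pasts, rep(1L, 200), centers, proj_fn, seed = 3)
  expect_true(all(tm$to == 1))
  expect_true(all(tm$majority_fraction == 1))
})
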