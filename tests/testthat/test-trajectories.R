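test_that("simulation is seed-deterministic and stationary", {
  m <- build_machine("even")
  a <- simulate(m, nsim = 200, seed = 5, length = 30)
  b <- simulate(m, nsim = 200, seed = 5, length = 30)
  expect_identical(a$seq, b$seq)

  # per-position symbol law matches the stationary emission law within 4 SE
  n <- 1e5
  ts <- simulate(m, nsim = n, seed = 1, length = 12)
  pi <- stationary_distribution(m)
  p1 <- as.vector(pi %*% m$emit)[2]           # P(X_t = "1") = 2/3
  for (pos in c(1, 6, 12)) {
    phat <- mean(ts$seq[, pos] == 2L)
    expect_lt(abs(phat - p1), 4 * sqrt(p1 * (1 - p1) / n))
  }
})

test_that("sampled sequences respect the support of the machine", {
  # Even Process: every maximal 1-run flanked by 0s has even length
  ts <- simulate(build_machine("even"), nsim = 2e4, seed = 1, length = 30)
  runs <- apply(ts$seq, 1, function(s) {
    r <- rle(s)
    any(r$values == 2L & r$lengths %% 2 == 1 &
          seq_along(r$values) > 1 & seq_along(r$values) < length(r$values))
  })
  expect_false(any(runs))

  # RIP: no sampled 3-gram outside the machine's positive-probability set
  m <- build_machine("rip")
  ts <- simulate(m, nsim = 2e4, seed = 7, length = 30)
  allowed <- names(which(colSums(unclass(causal_future_joint(m, 3))) > 0))
  grams <- unique(as.vector(vapply(1:28, function(t)
    paste0(ts$seq[, t] - 1L, ts$seq[, t + 1] - 1L, ts$seq[, t + 2] - 1L),
    character(nrow(ts$seq)))))
  expect_true(all(grams %in% allowed))

  # fair coin: P(1) = 0.5 +- 0.005 at n = 1e5 draws
  tc <- simulate(build_machine("iid_coin"), nsim = 4000, seed = 1, length = 30)
  expect_lt(abs(mean(tc$seq == 2L) - 0.5), 0.005)
})

test_that("Copy3 mirrors the past block exactly", {
  ts <- sample_copy3(2000, horizon = 15, seed = 3)
  expect_identical(ts$seq[, 16:30], ts$seq[, 15:1])
  freqs <- tabulate(ts$seq[, 1:15], nbins = 3) / (2000 * 15)
  expect_true(all(abs(freqs - 1 / 3) < 0.01))

  # horizon 1: block mutual information of the copy pair is ln 3
  t1 <- sample_copy3(500, horizon = 1, seed = 4)
  expect_equal(mutual_information(joint_table(diag(3) / 3)), log(3),
               tolerance = 1e-12)
  expect_identical(t1$seq[, 1], t1$seq[, 2])
})

test_that("trajectory files round-trip and report ragged lines", {
  ts <- simulate(build_machine("even"), nsim = 50, seed = 2, length = 30)
  f <- tempfile()
  write_trajectories(ts, f)
  back <- read_trajectories(f)
  expect_identical(back$seq, ts$seq)
  expect_identical(back$alphabet, c("0", "1"))   # inferred
  f2 <- tempfile()
  write_trajectories(back, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- tempfile()
  writeLines(c("0 1 0", "0 1"), bad)
  expect_error(read_trajectories(bad), "line 2")
})

test_that("splits partition the data disjointly", {
  ts <- simulate(build_machine("even"), nsim = 100, seed = 2, length = 10)
  sp <- split_trajectories(ts, n_val = 20, n_test = 30)
  expect_equal(nrow(sp$train$seq), 50)
  expect_equal(nrow(sp$val$seq), 20)
  expect_equal(nrow(sp$test$seq), 30)
  expect_identical(rbind(sp$train$seq, sp$val$seq, sp$test$seq), ts$seq)
})
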