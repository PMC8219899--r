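test_that("milestoning fills gaps with the last visited core", {
  # A-core, gap, B-core: gap frames get A
  ids <- c(1L, 1L, NA, NA, 2L, 2L)
  out <- milestone_assign(list(ids))[[1]]
  expect_equal(as.integer(out), c(1L, 1L, 1L, 1L, 2L, 2L))
  # frames before any core visit stay unassigned
  out2 <- milestone_assign(list(c(NA, NA, 1L, NA, 2L)))[[1]]
  expect_equal(as.integer(out2), c(NA, NA, 1L, 1L, 2L))
  # constant inside one core
  out3 <- milestone_assign(list(rep(3L, 5)))[[1]]
  expect_true(all(out3 == 3L))
  # a replica that never enters a core is dropped with a warning
  expect_warning(res <- milestone_assign(list(rep(NA_integer_, 4),
                                              c(1L, 1L))), "never enters")
  expect_length(res, 1)
})

test_that("milestoning is invariant to non-core frames inside a dwell", {
  a <- c(1L, 1L, 1L, 2L, 2L)
  b <- c(1L, NA, 1L, NA, 1L, 2L, NA, 2L)   # NAs inserted inside dwells
  fa <- milestone_assign(list(a))[[1]]
  fb <- milestone_assign(list(b))[[1]]
  expect_equal(unique(rle(as.integer(fa))$values),
               unique(rle(as.integer(fb))$values))
})

test_that("transition counts match closed forms and the naive oracle", {
  expect_equal(count_transitions(list(rep(1L, 10)), 1, n_states = 1)[1, 1], 9L)
  alt <- rep(c(1L, 2L), 10)
  C <- count_transitions(list(alt), 1)
  expect_equal(diag(C), c(0L, 0L))
  expect_equal(C[1, 2] + C[2, 1], 19L)
  set.seed(30)
  s <- sample.int(4, 500, replace = TRUE)
  for (lag in c(1, 3, 7))
    expect_equal(count_transitions(list(s), lag),
                 matrix(as.numeric(brute_counts(s, lag, 4)), 4, 4),
                 ignore_attr = TRUE)
  # counts never cross replica boundaries
  C2 <- count_transitions(list(c(1L, 1L), c(2L, 2L)), 1)
  expect_equal(C2[1, 2], 0)
  expect_error(count_transitions(list(1L), 2), "not shorter")
})

test_that("transition-matrix estimation matches the closed form", {
  C <- rbind(c(9, 1), c(1, 9))
  m <- estimate_msm(C, lag_ns = 1)
  expect_equal(m$T, rbind(c(0.9, 0.1), c(0.1, 0.9)), ignore_attr = TRUE)
  expect_equal(m$eigenvalues, c(1, 0.8))
  expect_equal(m$timescales_ns[1], -1 / log(0.8))
  expect_equal(m$pi, c(0.5, 0.5))
  # disconnected third state is excluded from the active set
  C3 <- rbind(c(9, 1, 0), c(1, 9, 0), c(0, 0, 5))
  m3 <- estimate_msm(C3, lag_ns = 1)
  expect_equal(m3$active_set, c(1, 2))
  expect_error(estimate_msm(matrix(-1, 1, 1)), "non-negative")
})

test_that("reversible estimation satisfies detailed balance and a real spectrum", {
  set.seed(31)
  C <- matrix(rpois(16, 20), 4, 4)
  m <- estimate_msm(C, lag_ns = 2)
  expect_equal(rowSums(m$T), rep(1, 4), tolerance = 1e-10)
  db <- outer(m$pi, rep(1, 4)) * m$T
  expect_equal(db, t(db), tolerance = 1e-8)
  expect_true(all(abs(Im(m$eigenvalues)) == 0))
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-8)
  expect_equal(as.numeric(m$pi %*% m$T), m$pi, tolerance = 1e-8)
})

test_that("a planted Markov chain is recovered within sampling error", {
  set.seed(32)
  # symmetric chain: uniform stationary vector, so the reversible
  # (symmetrised) estimator is unbiased for P itself
  P <- rbind(c(0.95, 0.03, 0.02),
             c(0.03, 0.95, 0.02),
             c(0.02, 0.02, 0.96))
  n <- 1e5
  s <- integer(n); s[1] <- 1L
  for (t in 2:n) s[t] <- sample.int(3, 1, prob = P[s[t - 1], ])
  m <- estimate_msm(count_transitions(list(s), 1), lag_ns = 1)
  for (i in 1:3) for (j in 1:3) {
    n_i <- sum(s[-n] == i)
    se <- sqrt(P[i, j] * (1 - P[i, j]) / n_i)
    expect_lt(abs(m$T[i, j] - P[i, j]), max(3 * se, 0.005))
  }
  # Chapman-Kolmogorov spot check: T(1)^2 vs T(2)
  m2 <- estimate_msm(count_transitions(list(s), 2), lag_ns = 2)
  expect_equal(m$T %*% m$T, m2$T, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("implied timescales are lag-independent for a Markov chain", {
  set.seed(33)
  P <- rbind(c(0.98, 0.02), c(0.03, 0.97))
  n <- 1e6
  u <- runif(n)
  s <- integer(n); s[1] <- 1L
  for (t in 2:n) {
    p_leave <- if (s[t - 1] == 1L) 0.02 else 0.03
    s[t] <- if (u[t] < p_leave) 3L - s[t - 1] else s[t - 1]
  }
  its <- implied_timescales(list(s), lags = c(1, 2, 5, 10), dt_ns = 1,
                            n_processes = 1)
  t2 <- its$table$t1_ns
  expect_lt((max(t2) - min(t2)) / mean(t2), 0.05)
  expect_true(its$converged[1])
  # analytic value: -1/log(1 - 0.02 - 0.03)
  expect_equal(mean(t2), -1 / log(0.95), tolerance = 0.05)
})

test_that("white-noise state sequences are flagged unconverged", {
  set.seed(34)
  s <- sample.int(3, 5e4, replace = TRUE)
  its <- implied_timescales(list(s), lags = c(1, 2, 5, 10), n_processes = 2)
  # no slow process: timescales on the lag scale, not constant
  expect_true(all(its$table$t1_ns < 20, na.rm = TRUE))
  expect_false(all(its$converged))
})

test_that("double-well Langevin MSM agrees with hand-counted crossings", {
  kT <- kB_ref * 300
  pot <- double_well_potential(3 * kT, 1)
  tr <- generate_langevin(pot, 2e5, 5e-4, seed = 35, stride = 5)
  x <- as.numeric(tr[, 1])
  cores1d <- list(c(-1.3, -0.7), c(0.7, 1.3))
  ids <- rep(NA_integer_, length(x))
  ids[x >= cores1d[[1]][1] & x <= cores1d[[1]][2]] <- 1L
  ids[x >= cores1d[[2]][1] & x <= cores1d[[2]][2]] <- 2L
  ct <- milestone_assign(list(ids))[[1]]
  C <- count_transitions(list(ct), 1)
  # hand-counted crossings on the milestoned sequence
  seq_ <- as.integer(ct[!is.na(ct)])
  trans12 <- sum(seq_[-length(seq_)] == 1L & seq_[-1] == 2L)
  trans21 <- sum(seq_[-length(seq_)] == 2L & seq_[-1] == 1L)
  expect_equal(C[1, 2], trans12)
  expect_equal(C[2, 1], trans21)
  expect_gt(trans12, 3)   # the well actually exchanges at this barrier
})
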