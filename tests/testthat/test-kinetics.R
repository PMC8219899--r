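test_that("unfolding classification follows threshold and persistence", {
  # constant low RMSD: censored at the trajectory end
  ft <- feature_trajectory(matrix(0.1, 100, 1, dimnames = list(NULL, "rmsd")),
                           dt_ns = 1)
  s <- classify_unfolding(ft)
  expect_equal(s$censored, 1L)
  expect_equal(s$time_ns, 100)
  # step to 0.3 nm at 30 ns that persists: event at 30 ns
  v <- c(rep(0.1, 30), rep(0.3, 70))
  ft2 <- feature_trajectory(matrix(v, ncol = 1, dimnames = list(NULL, "rmsd")),
                            dt_ns = 1)
  s2 <- classify_unfolding(ft2)
  expect_equal(s2$censored, 0L)
  expect_equal(s2$time_ns, 30)
  # a single-frame spike is filtered by the persistence window
  v3 <- c(rep(0.1, 50), 0.5, rep(0.1, 49))
  ft3 <- feature_trajectory(matrix(v3, ncol = 1, dimnames = list(NULL, "rmsd")),
                            dt_ns = 1)
  expect_equal(classify_unfolding(ft3, persistence = 2)$censored, 1L)
  # hydrogen-bond criterion: event when the bond stays broken
  hb <- c(rep(1, 40), rep(0, 60))
  ft4 <- feature_trajectory(matrix(hb, ncol = 1, dimnames = list(NULL, "287m")),
                            dt_ns = 1)
  s4 <- classify_unfolding(ft4, criterion = "287m")
  expect_equal(s4$time_ns, 40)
  expect_error(classify_unfolding(ft, criterion = "288m"), "missing")
})

test_that("survival curves are monotone steps with the right values", {
  d <- survival_data(c(10, 20), c(0, 0))
  sc <- survival_curve(d)
  expect_equal(sc$folded_fraction, c(1, 0.5, 0))
  # all censored: constant one
  d2 <- survival_data(c(220, 220), c(1, 1))
  sc2 <- survival_curve(d2)
  expect_true(all(sc2$folded_fraction == 1))
  expect_true(all(diff(sc$folded_fraction) <= 0))
  expect_equal(sc$folded_fraction[1], 1)
})

test_that("empirical survival approaches the exponential law", {
  d <- generate_unfolding_times(log(2) / 50, 1e6, 5000, seed = 50)
  sc <- survival_curve(d)
  dist <- max(abs(sc$folded_fraction - exp(-log(2) / 50 * sc$time_ns)))
  expect_lt(dist, 0.05)
})

test_that("censored exponential MLE matches closed forms", {
  # single event, no censoring: k = 1/t
  f1 <- fit_exponential(survival_data(40, 0))
  expect_equal(f1$k, 1 / 40)
  expect_equal(f1$t_half, 40 * log(2))
  # hand computation with one censored record
  d <- survival_data(c(50, 100, 150, 220), c(0, 0, 0, 1))
  f <- fit_exponential(d)
  expect_equal(f$k, 3 / 520)
  expect_equal(f$n_events, 3L)
  expect_equal(f$n_censored, 1L)
  expect_equal(f$sigma_k, f$k / sqrt(3))
  expect_equal(f$t_half, log(2) / f$k)
  # fully observed data: MLE reduces to 1/mean
  d2 <- survival_data(c(10, 30, 50), c(0, 0, 0))
  expect_equal(fit_exponential(d2)$k, 1 / 30)
  # no events: explicit no-event result, not an error
  f0 <- fit_exponential(survival_data(c(220, 220), c(1, 1)))
  expect_true(f0$no_events)
  expect_true(is.na(f0$k))
})

test_that("the rate is equivariant under time rescaling", {
  d <- survival_data(c(50, 100, 150, 220), c(0, 0, 0, 1))
  d_ps <- survival_data(d$time_ns * 1000, d$censored)
  expect_equal(fit_exponential(d_ps)$k * 1000, fit_exponential(d)$k)
})

test_that("MLE agrees with an established survival-model fit", {
  skip_if_not_installed("survival")
  d <- generate_unfolding_times(log(2) / 93, 220, 60, seed = 51)
  f <- fit_exponential(d)
  sr <- survival::survreg(
    survival::Surv(time_ns, 1 - censored) ~ 1, data = d,
    dist = "exponential")
  expect_equal(f$k, exp(-unname(coef(sr))), tolerance = 1e-6)
})

test_that("least-squares alternative tracks the MLE on clean data", {
  d <- generate_unfolding_times(log(2) / 80, 400, 200, seed = 52)
  fm <- fit_exponential(d, method = "mle")
  fl <- fit_exponential(d, method = "ls")
  expect_equal(fl$k, fm$k, tolerance = 0.15)
})

test_that("half-life coverage: planted 93 ns recovered within 2 sigma", {
  hits <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    d <- generate_unfolding_times(log(2) / 93, 220, 60, seed = 6000 + i)
    f <- fit_exponential(d)
    if (abs(f$t_half - 93) <= 2 * f$sigma_t_half) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("percent unfolded matches counts and the closed form", {
  d <- survival_data(c(10, 50, 100, 220), c(0, 0, 0, 1))
  expect_equal(percent_unfolded(d, 220), 75)
  expect_equal(percent_unfolded(survival_data(c(220, 220), c(1, 1)), 220), 0)
  k <- log(2) / 93
  d2 <- generate_unfolding_times(k, 220, 2000, seed = 53)
  p <- percent_unfolded(d2, 220)
  p_true <- 100 * (1 - exp(-220 * k))
  expect_lt(abs(p - p_true), 4 * 100 * sqrt(p_true / 100 * (1 - p_true / 100) / 2000))
  expect_error(percent_unfolded(d, 500), "horizon")
})

test_that("KS diagnostic is small for exponential data, large for bimodal", {
  d <- generate_unfolding_times(log(2) / 93, 220, 500, seed = 54)
  f <- fit_exponential(d)
  expect_lt(f$ks_distance, 0.1)
  bim <- survival_data(c(rep(10, 50), rep(200, 50)), rep(0, 100))
  expect_gt(fit_exponential(bim)$ks_distance, 0.2)
})
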