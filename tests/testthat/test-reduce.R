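test_that("PCA recovers the analytic eigenstructure of a known Gaussian", {
  set.seed(10)
  S <- rbind(c(2, 1), c(1, 2))
  L <- chol(S)
  X <- matrix(rnorm(2e4), ncol = 2) %*% L
  m <- fit_pca(X)
  expect_equal(m$eigenvalues, c(3, 1), tolerance = 0.05)
  pc1 <- m$components[, 1]
  expect_gt(abs(sum(pc1 * c(1, 1) / sqrt(2))), 0.99)
  # trace conservation: eigenvalue sum equals total feature variance
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-9)
  expect_equal(sum(m$explained), 1, tolerance = 1e-9)
})

test_that("isotropic input gives equal eigenvalues and rank deficiency warns", {
  set.seed(11)
  X <- matrix(rnorm(3e4), ncol = 3)
  ev <- fit_pca(X)$eigenvalues
  expect_lt(diff(range(ev)) / mean(ev), 0.1)
  Xdg <- cbind(X[, 1], X[, 1])   # rank 1
  expect_warning(m <- fit_pca(Xdg), "rank-deficient")
  expect_equal(ncol(m$components), 1)
})

test_that("projection is exact on the mean, identity and round trip", {
  set.seed(12)
  X <- matrix(rnorm(500 * 4), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  m <- fit_pca(X)
  # the mean projects to the origin
  expect_equal(as.numeric(predict(m, matrix(m$mean, 1,
                                            dimnames = list(NULL, names(m$mean))))),
               rep(0, 4), tolerance = 1e-12)
  # full-rank PCA round trip reconstructs the data
  Y <- predict(m, X)
  Xrec <- sweep(Y %*% t(m$components), 2, m$mean, "+")
  expect_lt(max(abs(Xrec - X)), 1e-9)
  expect_error(predict(m, X[, 1:2]), "missing")
})

test_that("joint and per-ensemble PCA agree when covariances match", {
  set.seed(13)
  L <- chol(rbind(c(3, 1), c(1, 1.5)))
  A <- matrix(rnorm(2e4), ncol = 2) %*% L
  B <- sweep(matrix(rnorm(2e4), ncol = 2) %*% L, 2, c(0.05, -0.05), "+")
  colnames(A) <- colnames(B) <- c("f1", "f2")
  joint <- fit_pca(list(A, B))
  sep <- fit_pca(A)
  cs <- abs(sum(joint$components[, 1] * sep$components[, 1]))
  expect_gt(cs, 0.99)
})

test_that("tICA matches the two-state closed form and kills white noise", {
  set.seed(14)
  p <- 0.02; n <- 60000
  z <- integer(n); z[1] <- 1L
  flip <- runif(n) < p
  for (t in 2:n) z[t] <- if (flip[t]) 3L - z[t - 1L] else z[t - 1L]
  mu <- rbind(c(0, 0, 0), c(2, 1, -1))
  X <- mu[z, ] + matrix(rnorm(3 * n, sd = 0.05), n, 3)
  ft <- feature_trajectory(X, dt_ns = 1)
  tstar <- -1 / log(1 - 2 * p)
  for (lag in c(5, 10)) {
    m <- fit_tica(ft, lag_ns = lag)
    n_eff <- n / (2 * tstar)
    se <- sqrt((1 - exp(-2 * lag / tstar)) / n_eff)
    expect_lt(abs(m$eigenvalues[1] - exp(-lag / tstar)), 3 * se)
  }
  # white noise: no memory at any lag
  W <- feature_trajectory(matrix(rnorm(3 * 20000), ncol = 3))
  mw <- fit_tica(W, lag_ns = 1)
  expect_true(all(abs(mw$eigenvalues) < 3 / sqrt(20000)))
})

test_that("tICA timescale is stable under lag doubling", {
  set.seed(15)
  p <- 0.01; n <- 100000
  z <- integer(n); z[1] <- 1L
  flip <- runif(n) < p
  for (t in 2:n) z[t] <- if (flip[t]) 3L - z[t - 1L] else z[t - 1L]
  X <- cbind(z * 1.0, -0.5 * z) + matrix(rnorm(2 * n, sd = 0.05), n, 2)
  ft <- feature_trajectory(X)
  t1 <- -5 / log(fit_tica(ft, lag_ns = 5)$eigenvalues[1])
  t2 <- -10 / log(fit_tica(ft, lag_ns = 10)$eigenvalues[1])
  expect_lt(abs(t2 - t1) / t1, 0.15)
})

test_that("collinear features are regularised without changing the spectrum", {
  set.seed(16)
  n <- 20000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  y <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  A <- cbind(a = x, b = y)
  B <- cbind(a = x, b = y, c = x)   # perfect collinearity
  la <- fit_tica(A, lag_ns = 2)$eigenvalues[1]
  lb <- fit_tica(B, lag_ns = 2)$eigenvalues[1]
  expect_equal(la, lb, tolerance = 1e-6)
})

test_that("tICA rejects lags not commensurate with the data", {
  ft <- feature_trajectory(matrix(rnorm(40), ncol = 2), dt_ns = 0.5)
  expect_error(fit_tica(ft, lag_ns = 0.3), "multiple")
  expect_error(fit_tica(ft, lag_ns = 25), "not shorter")
})

test_that("free-energy surfaces and difference densities are consistent", {
  set.seed(17)
  U <- cbind(runif(20000), runif(20000))
  s <- energy_surface(U, bins = 10)
  expect_equal(sum(s$population), 1, tolerance = 1e-12)
  # uniform sample: flat within sampling error; with ~200 counts per bin
  # the free-energy spread is of order 4/sqrt(200) per tail
  expect_lt(max(s$free_energy, na.rm = TRUE), 8 / sqrt(200))
  # identical ensembles: difference zero
  d0 <- difference_density(s, s)
  expect_true(all(d0$difference == 0))
  # two shifted Gaussians: difference integrates to zero
  brx <- seq(-5, 6, by = 0.25)
  a <- energy_surface(matrix(rnorm(20000), ncol = 2),
                      bins = list(brx, brx))
  b <- energy_surface(matrix(rnorm(20000, mean = 0.5), ncol = 2),
                      bins = list(brx, brx))
  d <- difference_density(a, b)
  expect_lt(abs(sum(d$difference)), 1e-12)
  # empty bins are NA, never zero, and the minimum is shifted to zero
  expect_true(anyNA(a$free_energy))
  expect_equal(min(a$free_energy, na.rm = TRUE), 0)
})
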