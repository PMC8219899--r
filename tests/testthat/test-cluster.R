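test_that("trivial clusterings match the definition", {
  set.seed(20)
  X <- matrix(rnorm(20, sd = 0.05), ncol = 2)
  # all points mutually within r, n_c = 0: one cluster
  cl <- fit_commonnn(X, r = 1, n_c = 0)
  expect_equal(cl$labels, rep(0L, 10))
  # impossible shared-neighbour requirement: everything noise
  cl2 <- fit_commonnn(X, r = 1, n_c = nrow(X) - 1)
  expect_true(all(cl2$labels == -1L))
  expect_error(fit_commonnn(X, r = 0, n_c = 0), "r must be")
})

test_that("two well-separated blobs give two clusters matching brute force", {
  set.seed(21)
  X <- rbind(matrix(rnorm(60, sd = 0.2), ncol = 2),
             matrix(rnorm(60, sd = 0.2), ncol = 2) + 5)
  cl <- fit_commonnn(X, r = 0.5, n_c = 2, min_members = 5)
  expect_equal(length(cl$sizes), 2)
  expect_identical(cl$labels, brute_cnn(X, 0.5, 2, 5))
})

test_that("partitions agree with the brute-force oracle on random instances", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(30:350, 1)
    d <- sample(1:4, 1)
    k <- sample(1:3, 1)
    centers <- matrix(rnorm(k * d, sd = 3), k, d)
    X <- centers[sample(k, n, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(n * d, sd = runif(1, 0.2, 0.8)), n, d)
    r <- runif(1, 0.3, 1.2)
    nc <- sample(0:6, 1)
    mm <- sample(1:8, 1)
    expect_identical(fit_commonnn(X, r, nc, mm)$labels, brute_cnn(X, r, nc, mm),
                     label = sprintf("instance n=%d d=%d r=%.2f nc=%d mm=%d",
                                     n, d, r, nc, mm))
  }
})

test_that("clustering is deterministic and permutation invariant", {
  set.seed(23)
  X <- rbind(matrix(rnorm(100, sd = 0.3), ncol = 2),
             matrix(rnorm(100, sd = 0.3), ncol = 2) + 3)
  a <- fit_commonnn(X, 0.6, 3, 5)$labels
  b <- fit_commonnn(X, 0.6, 3, 5)$labels
  expect_identical(a, b)
  perm <- sample(nrow(X))
  c_ <- fit_commonnn(X[perm, ], 0.6, 3, 5)$labels
  # same partition up to label renaming
  expect_equal(length(unique(a)), length(unique(c_)))
  for (k in unique(a[a >= 0])) {
    members <- which(a == k)
    mapped <- c_[match(members, perm)]
    expect_equal(length(unique(mapped)), 1)
  }
})

test_that("loosening the density requirement never fragments clusters", {
  set.seed(24)
  X <- rbind(matrix(rnorm(120, sd = 0.4), ncol = 2),
             matrix(rnorm(120, sd = 0.4), ncol = 2) + 4)
  n_with <- function(r, nc) length(fit_commonnn(X, r, nc, 5)$sizes)
  for (nc in c(8, 4, 2, 0))
    expect_lte(n_with(0.5, nc), n_with(0.5, nc + 2) + 0)
  expect_lte(n_with(0.9, 3), max(n_with(0.5, 3), n_with(0.9, 3)))
})

test_that("core selection and assignment respect noise", {
  set.seed(25)
  X <- rbind(matrix(rnorm(100, sd = 0.2), ncol = 2),
             matrix(rnorm(100, sd = 0.2), ncol = 2) + 4,
             matrix(rnorm(100, sd = 0.2), ncol = 2) + 8)
  cl <- fit_commonnn(X, 0.5, 2, 10)
  cores <- select_cores(cl, X)
  expect_equal(cores$n_cores, 3)
  expect_equal(sort(vapply(cores$members, nrow, 1L)),
               sort(cl$sizes))
  # points far from every core stay unassigned
  far <- rbind(c(2, 2), c(-50, -50))
  ids <- assign_cores(far, cores)
  expect_true(is.na(ids[2]))
  # single cluster: everything assigned trivially
  cl1 <- fit_commonnn(X[1:50, ], 1.5, 0, 1)
  cores1 <- select_cores(cl1, X[1:50, ])
  expect_true(all(!is.na(assign_cores(X[1:50, ], cores1))))
  # all-noise labelling is rejected with advice
  cln <- fit_commonnn(X, 0.5, 90, 10)
  expect_error(select_cores(cln, X), "noise")
})

test_that("per-cluster occupancy report matches planted schedules", {
  # bond present exactly in the frames of one cluster
  lab <- c(rep(0L, 60), rep(1L, 40))
  pres <- matrix(c(rep(1, 60), rep(0, 40)), ncol = 1,
                 dimnames = list(NULL, "K257s-D308s"))
  rep_ <- cluster_report(lab, pres)
  expect_equal(rep_$occupancy[rep_$cluster == "0"], 1.0)
  expect_equal(rep_$occupancy[rep_$cluster == "1"], 0.0)
  expect_equal(rep_$occupancy[rep_$cluster == "ensemble"], 0.6)
  expect_equal(rep_$weight[rep_$cluster == "0"], 0.6)
  # planted schedule via the synthetic toy, using true labels
  sched <- rbind(G = c(kd = 0.654), O = c(0.05), B = c(0.05))
  traj <- generate_hbond_toy(sched, 3000, seed = 26)
  gt <- attr(traj, "ground_truth")
  b <- gt$bonds[[1]]
  hb <- detect_hbonds(traj, hbond_spec(b$donor, b$hydrogen, b$acceptor, "kd"))
  rep2 <- cluster_report(gt$labels - 1L, hb$presence)
  occG <- rep2$occupancy[rep2$cluster == "0"]
  nG <- sum(gt$labels == 1)
  expect_lt(abs(occG - 0.654), 4 * sqrt(0.654 * 0.346 / nG))
  expect_error(cluster_report(lab[1:10], pres), "does not match")
})

test_that("clustering in coordinate space recovers hidden states", {
  sched <- rbind(A = c(b = 0.5), B = c(0.5))
  traj <- generate_hbond_toy(sched, 800, seed = 27, emission_sd = 0.05)
  gt <- attr(traj, "ground_truth")
  rep_atoms <- gt$reporter_atoms
  pts <- cbind(traj$xyz[, rep_atoms[1], 1], traj$xyz[, rep_atoms[1], 2],
               traj$xyz[, rep_atoms[1], 3])
  cl <- fit_commonnn(pts, r = 0.3, n_c = 3, min_members = 20)
  expect_equal(length(cl$sizes), 2)
  # adjusted agreement with the hidden labels
  tab <- table(cl$labels[cl$labels >= 0], gt$labels[cl$labels >= 0])
  agree <- max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
  expect_gt(agree, 0.9)
})
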