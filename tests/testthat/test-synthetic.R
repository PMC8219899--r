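test_that("harmonic Langevin sampling obeys equipartition and determinism", {
  pot <- harmonic_potential(100, temperature = 300)
  tr <- generate_langevin(pot, 1e6, 5e-4, seed = 11)
  expect_equal(var(tr[, 1]), kB_ref * 300 / 100, tolerance = 0.05)
  # same seed, bit-identical
  tr2 <- generate_langevin(pot, 1e4, 5e-4, seed = 99)
  tr3 <- generate_langevin(pot, 1e4, 5e-4, seed = 99)
  expect_identical(unclass(tr2), unclass(tr3))
})

test_that("zero-temperature limit descends to the potential minimum", {
  pot <- harmonic_potential(50, center = 0.7, temperature = 0)
  tr <- generate_langevin(pot, 5000, 1e-3, seed = 1, x0 = 2)
  expect_equal(unname(tr[nrow(tr), 1]), 0.7, tolerance = 1e-6)
})

test_that("unstable time steps are rejected, divergence is explicit", {
  pot <- harmonic_potential(1000, temperature = 300)
  expect_error(generate_langevin(pot, 100, 1e-3, seed = 1), "unstable")
  expect_error(harmonic_potential(-1), "stiffness")
  expect_error(double_well_potential(-5), "barrier")
  expect_error(harmonic_potential(10, friction = 0), "friction")
})

test_that("double-well sampler matches the Boltzmann stationary density", {
  kT <- kB_ref * 300
  pot <- double_well_potential(3 * kT, 1, temperature = 300)
  tr <- generate_langevin(pot, 1e6, 5e-4, seed = 5)
  x <- tr[, 1]
  breaks <- seq(-2.2, 2.2, length.out = 45)
  obs <- hist(pmax(pmin(x, 2.19), -2.19), breaks = breaks, plot = FALSE)$counts
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  pexp_ <- exp(-pot$U(mid) / kT)
  pexp_ <- pexp_ / sum(pexp_)
  keep <- pexp_ * length(x) >= 10
  chi2 <- sum((obs[keep] - length(x) * pexp_[keep])^2 /
                (length(x) * pexp_[keep]))
  # correlated samples inflate chi2; use the effective sample size
  n_eff <- length(x) * 5e-4 / attr(tr, "ground_truth")$timescale_ns
  chi2_eff <- chi2 * n_eff / length(x)
  p <- stats::pchisq(chi2_eff, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("ground truth travels with every generated artifact", {
  pot <- double_well_potential(10, 1)
  tr <- generate_langevin(pot, 1000, 1e-4, seed = 3)
  gt <- attr(tr, "ground_truth")
  expect_equal(gt$seed, 3)
  expect_true(is.finite(gt$timescale_ns))
  traces <- generate_rupture_traces(50, 600, 40, 10, n = 5, seed = 4)
  expect_length(attr(traces, "ground_truth")$rupture_force, 5)
  sd_ <- generate_unfolding_times(0.01, 220, 10, seed = 5)
  expect_equal(attr(sd_, "ground_truth")$t_half, log(2) / 0.01)
  tg <- generate_itc_thermogram(1e-4, -40, cell_conc = 1e-4,
                                syringe_conc = 1.5e-2, seed = 6)
  expect_equal(attr(tg, "ground_truth")$Kd, 1e-4)
})

test_that("noiseless rupture traces peak exactly at the planted force", {
  traces <- generate_rupture_traces(50, 600, f_rupture_sd = 0, noise_sd = 0,
                                    n = 1, seed = 1)
  expect_equal(max(traces[[1]]$force), 600)
  # cohort median of planted forces equals the brute-force median
  traces <- generate_rupture_traces(50, 600, f_rupture_sd = 50, noise_sd = 0,
                                    n = 40, seed = 2)
  gt <- attr(traces, "ground_truth")
  maxima <- vapply(traces, function(tr) max(tr$force), 1)
  expect_equal(median(maxima), median(gt$rupture_force))
  expect_error(generate_rupture_traces(-1, 600), "loading_rate")
})

test_that("unfolding-time generator censors at the simulation cap", {
  s0 <- generate_unfolding_times(0, 220, 30, seed = 1)
  expect_true(all(s0$censored == 1))
  expect_true(all(s0$time_ns == 220))
  # censored fraction matches the closed-form survival at the cap
  k <- log(2) / 93
  s <- generate_unfolding_times(k, 220, 2000, seed = 2)
  p_cens <- exp(-220 * k)
  expect_equal(mean(s$censored), p_cens,
               tolerance = 4 * sqrt(p_cens * (1 - p_cens) / 2000) / p_cens)
  # half-life definition: fraction unfolded by t_half is one half
  s2 <- generate_unfolding_times(log(2) / 100, 1e7, 4000, seed = 3)
  expect_equal(mean(s2$time_ns <= 100), 0.5, tolerance = 0.05)
})

test_that("ITC generator handles degenerate inputs and reports c-values", {
  tg0 <- generate_itc_thermogram(1e-4, 0, cell_conc = 1e-4,
                                 syringe_conc = 1.5e-2, seed = 1)
  expect_true(all(tg0$heat_ucal == 0))
  expect_error(generate_itc_thermogram(1e-4, -40, cell_conc = 1e-4,
                                       syringe_conc = 1.5e-2,
                                       cell_volume_ul = 0), "cell volume")
  gt <- attr(generate_itc_thermogram(1e-4, -40, cell_conc = 2e-4,
                                     syringe_conc = 1.5e-2, seed = 1),
             "ground_truth")
  expect_equal(gt$c_value, 2)
  expect_true(gt$low_c)
  gt2 <- attr(generate_itc_thermogram(1e-5, -40, cell_conc = 2e-4,
                                      syringe_conc = 1.5e-2, seed = 1),
              "ground_truth")
  expect_false(gt2$low_c)
})

test_that("pKa record generator plants coupling fractions and collapses at sd 0", {
  r0 <- generate_pka_records(500, 5.0, 0.5, 0, seed = 1)
  expect_equal(sum(r0$coupled), 0)
  rs <- generate_pka_records(300, 6.4, 0, 0.5, seed = 2)
  expect_true(all(rs$pka == 6.4))
  expect_error(generate_pka_records(10, 5, 0.5, 1.5), "coupling_fraction")
  r <- generate_pka_records(1e4, 6.4, 0.7, 0.74, seed = 3)
  expect_equal(mean(r$coupled), 0.74, tolerance = 3 * sqrt(0.74 * 0.26 / 1e4) / 0.74)
  expect_true(all(r$alt_a[r$coupled] > r$alt_b[r$coupled]))
})

test_that("hydrogen-bond toy trajectory honours its occupancy schedule", {
  sched <- rbind(G = c(b1 = 1.0, b2 = 0.654), O = c(1.0, 0.1), B = c(1.0, 0.1))
  traj <- generate_hbond_toy(sched, 2000, seed = 9)
  gt <- attr(traj, "ground_truth")
  specs <- lapply(gt$bonds, function(b)
    hbond_spec(b$donor, b$hydrogen, b$acceptor, b$label))
  hb <- detect_hbonds(traj, specs)
  # occupancy 1.0 scheduled everywhere -> detected 1.0
  expect_equal(unname(hb$occupancy["b1"]), 1.0)
  # state-dependent bond within binomial CI given the true labels
  inG <- gt$labels == 1
  occG <- mean(hb$presence[inG, "b2"])
  se <- sqrt(0.654 * (1 - 0.654) / sum(inG))
  expect_lt(abs(occG - 0.654), 4 * se)
  expect_error(generate_hbond_toy(rbind(c(1.5)), 10), "occupancies")
})
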