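test_that("quantum yield from lifetimes matches the lifetime ratio", {
  expect_equal(round(donor_quantum_yield(0.33, 3.5), 3), 0.094)
  expect_equal(donor_quantum_yield(2.2, 2.2), 1.0)
  expect_error(donor_quantum_yield(3.5, 0.33), "unphysical")
  expect_error(donor_quantum_yield(-1, 3.5), "positive")
})

test_that("Foerster radius matches the independent closed-form evaluation", {
  p <- sensor_params()
  # frozen oracle: sixth root of 9000 ln10 k2 QD J_cgs / (128 pi^5 N_A n^4)
  # evaluated independently with QD = 0.33/3.5, J = 3.22591e15, n = 1.4
  expect_equal(p$R0, 4.083574, tolerance = 1e-6)
  # rounded literature constant (8.79e-5 A^6) agrees to ~0.01%
  R0_lit <- (8.79e-5 * (2 / 3) * (0.33 / 3.5) * 3.22591e15 / 1.4^4)^(1 / 6) / 10
  expect_equal(p$R0, R0_lit, tolerance = 1e-3)
  # homogeneity: doubling J multiplies R0 by 2^(1/6)
  p2 <- fret_parameters(J = 2 * p$J, tau_D = 0.33, tau_DR = 3.5)
  expect_equal(p2$R0 / p$R0, 2^(1 / 6), tolerance = 1e-12)
  expect_error(forster_radius(list(Q_D = 0.1, kappa2 = 0, n = 1.4, J = 1e15)),
               "positive")
})

test_that("parameter-set invariants are enforced", {
  expect_error(fret_parameters(Q_D = 0.5, J = 3.22591e15,
                               tau_D = 0.33, tau_DR = 3.5), "inconsistent")
  expect_silent(fret_parameters(Q_D = 0.0943, J = 3.22591e15,
                                tau_D = 0.33, tau_DR = 3.5))
  expect_error(fret_parameters(J = 3.22591e15, tau_D = 3.5, tau_DR = 0.33),
               "unphysical")
  expect_error(fret_parameters(J = -1, tau_D = 0.33, tau_DR = 3.5), "J")
})

test_that("transfer rate follows the sixth-power law around R0", {
  p <- sensor_params()
  expect_equal(rate_constant(p$R0, p), 1 / p$tau_D, tolerance = 1e-12)
  expect_equal(rate_constant(2 * p$R0, p), (1 / p$tau_D) / 64, tolerance = 1e-12)
  expect_equal(rate_constant(p$R0 / 2, p), 64 / p$tau_D, tolerance = 1e-12)
  expect_error(rate_constant(0, p), "positive")
})

test_that("explicit-constant and R0 routes agree over 0.5-20 nm", {
  p <- sensor_params()
  r <- seq(0.5, 20, length.out = 200)
  k1 <- rate_constant(r, p)
  k2 <- rate_constant_explicit(r, p)
  expect_lt(max(abs(k1 - k2) / k2), 1e-6)
})

test_that("efficiency and quenched lifetime follow the FRET identities", {
  tau_D <- 0.33
  expect_equal(efficiency_from_rate(1 / tau_D, tau_D), 0.5)
  expect_equal(efficiency_from_rate(0, tau_D), 0)
  expect_equal(efficiency_from_rate(63 / tau_D, tau_D), 63 / 64)
  expect_error(efficiency_from_rate(-1, tau_D), "nonnegative")

  expect_equal(lifetime_da(tau_D, 0), tau_D)
  expect_equal(lifetime_da(tau_D, 1), 0)
  # the sensor's ensemble-average efficiency of 43% implies 0.1881 ms
  expect_equal(lifetime_da(0.33, 0.43), 0.1881)
  expect_equal(round(lifetime_da(0.33, 0.43), 2), 0.19)
  expect_error(lifetime_da(tau_D, 1.1), "\\[0, 1\\]")
})

test_that("efficiency decreases and lifetime increases with distance", {
  p <- sensor_params()
  r <- seq(0.5, 15, length.out = 100)
  E <- efficiency_from_rate(rate_constant(r, p), p$tau_D)
  expect_true(all(diff(E) < 0))
  expect_true(all(diff(lifetime_da(p$tau_D, E)) > 0))
  expect_true(all(E >= 0 & E <= 1))
})

test_that("E(R0) = 1/2 for arbitrary valid parameter sets", {
  set.seed(42)
  for (i in 1:20) {
    p <- fret_parameters(Q_D = runif(1, 0.01, 1), kappa2 = runif(1, 0.1, 4),
                         n = runif(1, 1.2, 1.6), J = 10^runif(1, 13, 17),
                         tau_D = runif(1, 0.05, 5))
    expect_equal(efficiency_from_rate(rate_constant(p$R0, p), p$tau_D), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("distance series files import with validation", {
  p1 <- write_lines_tmp(c("1.2", "3.4", "2.2"))
  ens <- read_distance_series(p1)
  expect_equal(length(ens), 3L)
  expect_null(ens$timestamps)
  expect_equal(sum(ens$weights), 1)

  p2 <- write_lines_tmp(c("0.0 1.2", "0.1 3.4"))
  ens2 <- read_distance_series(p2)
  expect_equal(ens2$timestamps, c(0, 0.1))
  expect_equal(ens2$distances, c(1.2, 3.4))

  p3 <- write_lines_tmp(c("1.2", "0.0"))
  expect_error(read_distance_series(p3), "row 2")

  out <- tempfile()
  write_distance_series(ens2, out)
  expect_equal(read_distance_series(out)$distances, ens2$distances)
})

test_that("ensemble summaries respect weights and exact FRET identities", {
  p <- sensor_params()
  # degenerate distribution at R0: E = 1/2, tau_DA = tau_D/2
  degen <- distance_ensemble(rep(p$R0, 5))
  res <- ensemble_fret(degen, p)
  expect_equal(res$mean_E, 0.5, tolerance = 1e-12)
  expect_equal(res$mean_tauDA, p$tau_D / 2, tolerance = 1e-12)

  # equal mixture of a collapsed and a fully extended conformation
  mix <- distance_ensemble(c(1e-3, 1e3))
  expect_equal(ensemble_fret(mix, p)$mean_E, 0.5, tolerance = 1e-6)

  # weighted means: weight everything onto one frame
  wens <- distance_ensemble(c(2, 8), weights = c(1, 0))
  E2 <- efficiency_from_rate(rate_constant(2, p), p$tau_D)
  expect_equal(ensemble_fret(wens, p)$mean_E, E2, tolerance = 1e-12)

  expect_error(distance_ensemble(numeric(0)), "nonempty")
  expect_error(distance_ensemble(c(1, -2)), "position 2")
})

test_that("mean_tauDA equals tau_D(1 - mean_E) to machine precision", {
  p <- sensor_params()
  set.seed(7)
  for (i in 1:10) {
    ens <- distance_ensemble(runif(200, 0.5, 12),
                             weights = runif(200))
    res <- ensemble_fret(ens, p)
    expect_equal(res$mean_tauDA, p$tau_D * (1 - res$mean_E),
                 tolerance = 1e-15)
    expect_true(all(res$E >= 0 & res$E <= 1))
    expect_true(all(res$tau_DA > 0 & res$tau_DA <= p$tau_D))
  }
})

test_that("cumulative curves are nondecreasing from 0 to 1", {
  p <- sensor_params()
  set.seed(11)
  ens <- distance_ensemble(rlnorm(500, log(3), 0.4))
  res <- ensemble_fret(ens, p)
  for (cdf in list(res$r_cdf, res$tau_cdf)) {
    expect_true(all(diff(cdf$p) >= 0))
    expect_gt(cdf$p[1], 0)
    expect_equal(cdf$p[nrow(cdf)], 1, tolerance = 1e-12)
  }
  # histogram densities integrate to ~1
  h <- res$r_hist
  expect_equal(sum(h$density * (h$mid[2] - h$mid[1])), 1, tolerance = 0.05)
})

test_that("experimental-lifetime efficiency is near the quoted ensemble value", {
  # efficiency from the two measured lifetimes 0.33 -> 0.18 ms
  E_exp <- 1 - 0.18 / 0.33
  expect_equal(E_exp, 0.4545, tolerance = 1e-3)
  # within 2 percentage points of the 44% quoted from unrounded lifetimes
  expect_lt(abs(E_exp - 0.44), 0.02)
})
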