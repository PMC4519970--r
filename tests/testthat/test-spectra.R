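test_that("spectrum files parse, sort, and reject bad input", {
  p <- write_lines_tmp(c("# comment", "500,0.0", "545,1.0", "600,0.0"))
  s <- read_spectrum(p, "emission")
  expect_s3_class(s, "spectrum")
  expect_equal(nrow(s), 3L)
  expect_equal(s$wavelength, c(500, 545, 600))

  # out-of-order rows are re-sorted ascending
  p2 <- write_lines_tmp(c("600 0.1", "500 0.5", "550 0.2"))
  s2 <- read_spectrum(p2, "emission")
  expect_equal(s2$wavelength, c(500, 550, 600))
  expect_equal(s2$value, c(0.5, 0.2, 0.1))

  # duplicated wavelength violates the grid invariant
  p3 <- write_lines_tmp(c("545 1", "545 2"))
  expect_error(read_spectrum(p3, "emission"), "duplicate")

  # non-numeric rows name the offending line; empty files error
  p4 <- write_lines_tmp(c("500 0.1", "oops 0.2"))
  expect_error(read_spectrum(p4, "emission"), "line 2")
  p5 <- write_lines_tmp(character(0))
  expect_error(read_spectrum(p5, "emission"), "empty")

  # writer emits the dialect the reader consumes (round trip)
  out <- tempfile()
  write_spectrum(s2, out)
  expect_equal(read_spectrum(out, "emission")$value, s2$value)
})

test_that("negative absorbance and extinction are rejected", {
  expect_error(spectrum(c(500, 510), c(0.1, -0.1), "absorbance"), "nonnegative")
  expect_error(spectrum(c(500, 510), c(1, -1), "extinction"), "nonnegative")
  expect_silent(spectrum(c(500, 510), c(1, -1), "emission"))
})

test_that("resampling onto a common grid interpolates without extrapolating", {
  a <- spectrum(400:700, rep(1, 301), "emission")
  b <- spectrum(500:800, rep(2, 301), "emission")
  rs <- resample_common_grid(a, b, step = 1)
  expect_equal(rs$a$wavelength, seq(500, 700, 1))
  expect_equal(nrow(rs$a), 201L)

  # identical grids reproduce the inputs
  rs2 <- resample_common_grid(a, a, step = 1)
  expect_equal(rs2$a$value, a$value)
  expect_equal(rs2$b$value, a$value)

  # linear data is interpolated exactly at midpoints
  lin <- spectrum(seq(500, 600, 10), seq(500, 600, 10), "emission")
  rs3 <- resample_common_grid(lin, lin, step = 5)
  expect_equal(rs3$a$value, rs3$a$wavelength)

  expect_error(resample_common_grid(
    spectrum(400:450, rep(1, 51), "emission"),
    spectrum(500:550, rep(1, 51), "emission")), "overlap")
})

test_that("overlap integral matches the closed-form boxcar oracle", {
  d <- boxcar_spectrum(3, "emission")       # arbitrary constant height
  e <- boxcar_spectrum(1e5, "extinction")
  res <- overlap_integral(d, e, step = 1)
  # oracle: normalized constant donor on [540,550] -> J = 1e5/10 * int lambda^4
  J_exact <- 1e5 * (550^5 - 540^5) / 5 / 10
  expect_equal(res$J, J_exact, tolerance = 1e-4)
  expect_equal(res$wavelength_range, c(540, 550))
})

test_that("overlap integral is donor-normalised and linear in extinction", {
  d <- synth_spectra("tb_emission")
  e <- synth_spectra("rfp_extinction")
  J1 <- overlap_integral(d, e)$J
  d2 <- spectrum(d$wavelength, 2 * d$value, "emission")
  e2 <- spectrum(e$wavelength, 2 * e$value, "extinction")
  expect_equal(overlap_integral(d2, e)$J, J1, tolerance = 1e-12)
  expect_equal(overlap_integral(d, e2)$J, 2 * J1, tolerance = 1e-12)

  disjoint_d <- spectrum(400:450, rep(1, 51), "emission")
  disjoint_e <- spectrum(500:550, rep(1e4, 51), "extinction")
  expect_error(overlap_integral(disjoint_d, disjoint_e), "overlap")
  zero_d <- spectrum(540:550, rep(0, 11), "emission")
  expect_error(overlap_integral(zero_d, e), "zero area")
})

test_that("overlap quadrature converges under step halving", {
  d <- synth_spectra("tb_emission")
  e <- synth_spectra("rfp_extinction")
  J1 <- overlap_integral(d, e, step = 1)$J
  Jh <- overlap_integral(d, e, step = 0.5)$J
  expect_lt(abs(J1 - Jh) / Jh, 0.001)
})

test_that("reabsorption correction applies 10^(D/2) per wavelength", {
  lam <- 500:600
  meas <- spectrum(lam, rep(100, length(lam)), "emission")
  # zero optical density leaves the spectrum unchanged
  d0 <- spectrum(lam, rep(0, length(lam)), "absorbance")
  expect_equal(inner_filter_correct(meas, d0)$value, meas$value)
  # D = 2 -> x10; D = 0.30103 (= log10 2) -> x sqrt(2)
  d2 <- spectrum(lam, rep(2, length(lam)), "absorbance")
  expect_equal(inner_filter_correct(meas, d2)$value[1], 1000)
  m50 <- spectrum(lam, rep(50, length(lam)), "emission")
  dd <- spectrum(lam, rep(0.30103, length(lam)), "absorbance")
  expect_equal(inner_filter_correct(m50, dd)$value[1], 70.71, tolerance = 2e-4)
  # correction never decreases intensity when D >= 0
  dr <- spectrum(lam, runif(length(lam), 0, 1), "absorbance")
  expect_true(all(inner_filter_correct(meas, dr)$value >= meas$value))
})

test_that("photobleach subtraction recovers an injected band and counts clamps", {
  lam <- 500:700
  base <- spectrum(lam, 10 + 0.01 * (lam - 500), "emission")
  band <- 5 * exp(-(lam - 606)^2 / (2 * 12^2))
  full <- spectrum(lam, base$value + band, "emission")

  self <- subtract_spectra(full, full)
  expect_true(all(self$value == 0))

  rec <- subtract_spectra(full, base)
  expect_equal(rec$value, band, tolerance = 1e-10)
  expect_equal(attr(rec, "n_clamped"), 0L)

  # bleached > full somewhere -> clamped zeros, counted
  noisy_bleach <- spectrum(lam, base$value + band +
                             c(rep(0, 100), rep(1, 101)), "emission")
  cl <- subtract_spectra(full, noisy_bleach)
  expect_true(all(cl$value >= 0))
  expect_gt(attr(cl, "n_clamped"), 0L)
})

test_that("band recovery survives mismatched grids up to interpolation error", {
  lam_f <- seq(500, 700, 1)
  lam_b <- seq(500.5, 699.5, 1)       # offset grid forces interpolation
  band <- function(l) 5 * exp(-(l - 606)^2 / (2 * 12^2))
  base <- function(l) 10 + 0.01 * (l - 500)
  full <- spectrum(lam_f, base(lam_f) + band(lam_f), "emission")
  bleach <- spectrum(lam_b, base(lam_b), "emission")
  rec <- subtract_spectra(full, bleach)
  max_slope <- max(abs(diff(band(lam_f))))
  expect_lt(max(abs(rec$value - band(rec$wavelength))), 1 * max_slope)
})
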