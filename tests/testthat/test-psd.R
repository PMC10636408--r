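test_that("welch_psd concentrates a sinusoid's power at its frequency", {
  dt <- 2.13; n <- 250; f0 <- 0.1
  x <- sin(2 * pi * f0 * dt * (0:(n - 1)))
  psd <- welch_psd(bold_series(x, dt))
  expect_lt(abs(psd$freqs[which.max(psd$power)] - f0), 1 / (64 * dt))
  # off-band (0.15 Hz) sinusoid leaves the 0.1 Hz bin near-empty
  x2 <- sin(2 * pi * 0.15 * dt * (0:(n - 1)))
  psd2 <- welch_psd(bold_series(x2, dt))
  i0 <- which.min(abs(psd2$freqs - f0))
  expect_lt(psd2$power[i0], 0.01 * max(psd2$power))
})

test_that("welch_psd of a constant series is all zero (DC excluded)", {
  psd <- welch_psd(bold_series(rep(3, 250), 2.13))
  expect_true(all(psd$power == 0))
})

test_that("welch_psd rejects series shorter than one window", {
  expect_error(welch_psd(bold_series(rnorm(50), 2.13), window_len = 64),
               "shorter than one window")
})

test_that("band integration conserves total power and groups bins", {
  psd <- welch_psd(bold_series(rnorm(250), 2.13))
  b <- integrate_bands(psd, 0.02)
  expect_equal(sum(b$power), sum(psd$power))
  expect_equal(sum(b$n_bins), length(psd$freqs))
  # uniform 0.01 Hz spacing, 0.02 Hz bands -> two bins per band
  u <- spectral_density(seq(0.01, 0.2, 0.01), rep(1, 20))
  bu <- integrate_bands(u, 0.02)
  expect_true(all(bu$power == 2))
  expect_equal(bu$freqs, seq(0.01, 0.19, 0.02))
  expect_error(integrate_bands(u, 0.005), "not wider")
})

test_that("banded and raw spectra give concordant, comparably stable fits", {
  # banding guards against sparse/zero-power bins; with the band-mean
  # density fit its sampling variance matches the raw fit closely
  reps <- 150
  fits <- vapply(seq_len(reps), function(i) {
    s <- simulate_fgn(fgn_spec(0.8), seed = 900 + i)
    psd <- welch_psd(s)
    c(fit_powerlaw(integrate_bands(psd))$hurst, fit_powerlaw(psd)$hurst)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - mean(fits[2, ])), 0.03)
  ratio <- stats::var(fits[1, ]) / stats::var(fits[2, ])
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.3)
  expect_gt(stats::cor(fits[1, ], fits[2, ]), 0.9)
})

test_that("fit_powerlaw is exact on an exact power law", {
  f <- seq(0.02, 0.22, 0.02)
  ft <- fit_powerlaw(spectral_density(f, f^-0.8))
  expect_equal(ft$beta, 0.8, tolerance = 1e-10)
  expect_equal(ft$hurst, 0.9, tolerance = 1e-10)
  expect_equal(ft$r_squared, 1, tolerance = 1e-10)
  expect_true(ft$model_ok)
})

test_that("fit_powerlaw flags the non-fGn regime and poor fits", {
  f <- seq(0.02, 0.22, 0.02)
  expect_false(fit_powerlaw(spectral_density(f, f^-1.6))$model_ok)  # fBm-like
  set.seed(4)
  wig <- spectral_density(f, exp(stats::rnorm(length(f), 0, 2)))
  expect_false(fit_powerlaw(wig)$model_ok || fit_powerlaw(wig)$r_squared >= 0.9)
})

test_that("fit_powerlaw error paths: few bands, non-positive power", {
  f <- seq(0.02, 0.22, 0.02)
  expect_error(fit_powerlaw(spectral_density(f[1:3], f[1:3]^-1)), ">= 4")
  p <- f^-1; p[3] <- 0
  expect_warning(ft <- fit_powerlaw(spectral_density(f, p)), "non-positive")
  expect_equal(ft$n_points, length(f) - 1L)
  expect_error(fit_powerlaw(spectral_density(f, f^-1), f_min = 0.3,
                            f_max = 0.1), "below")
})

test_that("beta to Hurst mapping is (beta + 1) / 2", {
  expect_equal(beta_to_hurst(0), 0.5)
  expect_equal(beta_to_hurst(1), 1.0)
  expect_equal(beta_to_hurst(-1), 0.0)
})

test_that("white-noise mean spectrum is flat in log-log", {
  reps <- 200
  set.seed(21)
  lp <- 0
  for (i in seq_len(reps)) {
    b <- integrate_bands(welch_psd(bold_series(stats::rnorm(250), 2.13)))
    lp <- lp + b$power / b$n_bins
  }
  sel <- b$freqs >= 0.015 & b$freqs <= 0.225
  slope <- stats::coef(stats::lm(log(lp[sel] / reps) ~ log(b$freqs[sel])))[[2]]
  expect_lt(abs(slope), 0.05)
})

test_that("scaling estimates are invariant to amplitude and offset", {
  s <- simulate_fgn(fgn_spec(0.7), seed = 31)
  s2 <- bold_series(5 * s$values + 100, s$dt)
  expect_equal(hurst_psd(s)$hurst, hurst_psd(s2)$hurst, tolerance = 1e-12)
  expect_equal(dfa(s)$hurst, dfa(s2)$hurst, tolerance = 1e-12)
  expect_equal(wavelet_monofractal(s)$hurst, wavelet_monofractal(s2)$hurst,
               tolerance = 1e-12)
})

test_that("sensitivity to frequency bounds is small for scaling signals", {
  # exact power law: identical H across every bound pair
  f <- seq(0.005, 0.23, 0.005)
  tab <- sensitivity_bounds(spectral_density(f, f^-0.6))
  expect_equal(nrow(tab), 16L)
  expect_true(all(abs(tab$hurst - 0.8) < 1e-10))
  # fGn cohort: median spread across bounds stays under 0.1
  spread <- vapply(1:40, function(i) {
    s <- simulate_fgn(fgn_spec(0.7), seed = 600 + i)
    tb <- sensitivity_bounds(s)
    max(tb$hurst) - min(tb$hurst)
  }, numeric(1))
  expect_lt(stats::median(spread), 0.1)
  expect_error(sensitivity_bounds(f, lower_bounds = 0.2, upper_bounds = 0.1),
               "below every upper")
})
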