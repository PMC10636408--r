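test_that("DFA recovers the white-noise exponent 0.5", {
  h <- fgn_estimates(function(s) dfa(s)$hurst, 0.5, n = 1024, reps = 60,
                     seed0 = 200)
  expect_lt(abs(mean(h) - 0.5), 0.05)
})

test_that("DFA recovers persistent fGn scaling", {
  h <- fgn_estimates(function(s) dfa(s)$hurst, 0.8, n = 2048, reps = 60,
                     seed0 = 300)
  expect_lt(abs(mean(h) - 0.8), 0.05)
})

test_that("DFA detrending: exact offset immunity, ramp immunity at order 2", {
  s <- simulate_fgn(fgn_spec(0.6, n_samples = 1024), seed = 401)
  shifted <- bold_series(s$values + 50, s$dt)
  expect_equal(dfa(shifted)$hurst, dfa(s)$hurst, tolerance = 1e-12)
  # a ramp in the signal is a quadratic trend in the profile: removed by
  # order-2 box detrending
  diffs <- vapply(1:25, function(i) {
    si <- simulate_fgn(fgn_spec(0.6, n_samples = 1024), seed = 400 + i)
    ramp <- bold_series(si$values + seq(0, 5, length.out = 1024), si$dt)
    dfa(ramp, detrend_order = 2)$hurst - dfa(si, detrend_order = 2)$hurst
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("DFA rejects infeasible box grids", {
  expect_error(dfa(bold_series(rnorm(20), 1)), "below 4")
  expect_error(dfa(bold_series(rnorm(256), 1), min_box = 8, max_box = 200),
               "infeasible")
})

test_that("wavelet energies of white noise are flat across octaves", {
  h <- fgn_estimates(function(s) wavelet_monofractal(s)$hurst, 0.5,
                     n = 1024, reps = 60, seed0 = 500)
  expect_lt(abs(mean(h) - 0.5), 0.05)
  b <- fgn_estimates(function(s) wavelet_monofractal(s)$beta, 0.5,
                     n = 1024, reps = 60, seed0 = 500)
  expect_lt(abs(mean(b)), 0.1)
})

test_that("wavelet monofractal estimate recovers fGn H", {
  h <- fgn_estimates(function(s) wavelet_monofractal(s)$hurst, 0.7,
                     n = 4096, reps = 50, seed0 = 600)
  expect_lt(abs(mean(h) - 0.7), 0.05)
})

test_that("db2 and db3 give concordant estimates", {
  d <- vapply(1:40, function(i) {
    s <- simulate_fgn(fgn_spec(0.7, n_samples = 2048), seed = 700 + i)
    wavelet_monofractal(s, wavelet = "db2")$hurst -
      wavelet_monofractal(s, wavelet = "db3")$hurst
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.05)
})

test_that("wavelet octave preconditions are enforced", {
  expect_error(wavelet_monofractal(bold_series(rnorm(64), 1), j_max = 6),
               "j_max")
  expect_error(wavelet_monofractal(bold_series(rnorm(64), 1)), "few octaves")
  expect_error(wavelet_monofractal(bold_series(rnorm(512), 1),
                                   wavelet = "sym9"), "unknown wavelet")
})

test_that("fGn is monofractal: c2 centers on zero, c1 near H", {
  cc <- vapply(1:40, function(i) {
    s <- simulate_fgn(fgn_spec(0.7, n_samples = 4096), seed = 800 + i)
    w <- wavelet_leader_multifractal(s)
    c(w$c1, w$c2)
  }, numeric(2))
  expect_lt(abs(mean(cc[2, ])), 0.05)
  expect_lt(abs(mean(cc[1, ]) - 0.7), 0.1)
})

test_that("multifractal random walk yields negative c2 of the right size", {
  lambda2 <- 0.05
  c2 <- vapply(1:40, function(i)
    wavelet_leader_multifractal(simulate_mrw(4096, lambda2, seed = 900 + i))$c2,
    numeric(1))
  expect_lt(mean(c2), 0)
  expect_gt(abs(mean(c2)), lambda2 / 2)
  expect_lt(abs(mean(c2)), lambda2 * 2)
})

test_that("degenerate signals hit the leader error path", {
  expect_error(wavelet_leader_multifractal(bold_series(rep(1, 1024), 1)),
               "degenerate")
})

test_that("estimators rank series concordantly across the H range", {
  Hs <- rep(c(0.3, 0.5, 0.7, 0.9), each = 12)
  ests <- t(vapply(seq_along(Hs), function(i) {
    s <- simulate_fgn(fgn_spec(Hs[i], n_samples = 512), seed = 1000 + i)
    c(psd = hurst_psd(s)$hurst, dfa = dfa(s)$hurst,
      wma = wavelet_monofractal(s)$hurst)
  }, numeric(3)))
  rk <- stats::cor(ests, method = "spearman")
  expect_true(all(rk[upper.tri(rk)] >= 0.8))
})
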