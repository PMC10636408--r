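dt_study <- 2.13

sine_series <- function(f0, n = 250, amp = 1)
  bold_series(amp * sin(2 * pi * f0 * dt_study * (0:(n - 1))), dt_study)

test_that("ALFF is band-selective and scales with squared amplitude", {
  in_band <- alff(sine_series(0.05))
  out_band <- alff(sine_series(0.15))
  expect_gt(in_band, 50 * out_band)
  expect_equal(alff(sine_series(0.05, amp = 2)) / in_band, 4,
               tolerance = 1e-6)
  # offset invariance
  s <- sine_series(0.05)
  expect_equal(alff(bold_series(s$values + 10, s$dt)), in_band,
               tolerance = 1e-10)
})

test_that("fALFF is a proportion: ~1 in band, ~0 out of band", {
  expect_gt(falff(sine_series(0.05)), 0.9)
  expect_lt(falff(sine_series(0.15)), 0.1)
  s <- sine_series(0.05)
  expect_equal(falff(bold_series(3 * s$values, s$dt)), falff(s),
               tolerance = 1e-12)
})

test_that("white-noise ALFF and fALFF match the flat-spectrum oracle", {
  nyq <- 1 / (2 * dt_study)
  reps <- 200
  set.seed(8)
  vals <- vapply(seq_len(reps), function(i) {
    s <- bold_series(stats::rnorm(250), dt_study)
    tot <- sum(integrate_bands(welch_psd(s))$power)
    c(falff(s), alff(s) / tot)
  }, numeric(2))
  # fALFF ~ covered band fraction; band centers 0.03-0.07 cover (0.02, 0.08]
  expect_lt(abs(mean(vals[1, ]) - 0.06 / nyq), 0.02)
  # ALFF ~ band fraction x total summed power (flat spectrum)
  expect_lt(abs(mean(vals[2, ]) - 0.06 / nyq), 0.02)
})

test_that("cubic ROI has 27 voxels before masking and intersects the mask", {
  mask <- array(TRUE, c(7, 7, 7))
  roi <- cubic_roi(c(3, 3, 3), mask)
  expect_equal(roi$n_requested, 27L)
  expect_length(roi$member_voxels, 27L)
  mask[1:3, , ] <- FALSE
  roi2 <- cubic_roi(c(3, 3, 3), mask)   # 0-based center at x=3 -> 1-based 4
  expect_length(roi2$member_voxels, 18L)
  expect_error(cubic_roi(c(0, 0, 0), array(FALSE, c(7, 7, 7))), "no voxels")
})

test_that("local connectivity: identical series give 1, hand-built mean", {
  d <- c(3, 1, 1); mask <- array(TRUE, d)
  base <- sin(seq_len(64))
  dat <- array(0, c(d, 64))
  for (i in 1:3) dat[i, 1, 1, ] <- base
  v <- volume_set(dat, mask, 3, dt_study)
  roi <- cubic_roi(c(1, 0, 0), mask)
  expect_equal(local_connectivity(v, roi), 1, tolerance = 1e-12)
  # three series with pairwise correlations {r, 0, -r} average to 0
  set.seed(10)
  e1 <- stats::rnorm(400); e2 <- stats::rnorm(400)
  a <- e1; b <- 0.6 * e1 + sqrt(1 - 0.36) * e2; c3 <- -b
  dat2 <- array(0, c(d, 400))
  dat2[1, 1, 1, ] <- a; dat2[2, 1, 1, ] <- b; dat2[3, 1, 1, ] <- c3
  v2 <- volume_set(dat2, mask, 3, dt_study)
  r <- stats::cor(a, b)
  expect_equal(local_connectivity(v2, cubic_roi(c(1, 0, 0), mask)),
               (r + stats::cor(a, c3) + (-1)) / 3, tolerance = 1e-12)
})

test_that("independent voxels have near-zero mean local connectivity", {
  d <- c(3, 3, 3); mask <- array(TRUE, d)
  set.seed(12)
  lc <- vapply(1:100, function(i) {
    v <- volume_set(array(stats::rnorm(27 * 200), c(d, 200)), mask, 3,
                    dt_study)
    local_connectivity(v, cubic_roi(c(1, 1, 1), mask))
  }, numeric(1))
  expect_lt(abs(mean(lc)), 0.01)
})

test_that("global connectivity is 1 when all mask voxels equal the ROI mean", {
  d <- c(4, 4, 1); mask <- array(TRUE, d)
  base <- stats::rnorm(128)
  dat <- array(rep(base, each = 16), c(d, 128))
  v <- volume_set(dat, mask, 3, dt_study)
  roi <- cubic_roi(c(1, 1, 0), mask)
  expect_equal(global_connectivity(v, roi), 1, tolerance = 1e-12)
  # mask == roi must fail
  small <- array(TRUE, c(3, 3, 1))
  vv <- volume_set(array(stats::rnorm(9 * 64), c(3, 3, 1, 64)), small, 3,
                   dt_study)
  expect_error(global_connectivity(vv, cubic_roi(c(1, 1, 0), small)),
               "empty")
})

test_that("null global connectivity shows the |r| bias that shrinks with n", {
  d <- c(3, 3, 2); mask <- array(TRUE, d)
  set.seed(13)
  gbar <- vapply(c(64, 512), function(n) {
    mean(vapply(1:30, function(i) {
      v <- volume_set(array(stats::rnorm(18 * n), c(d, n)), mask, 3, dt_study)
      global_connectivity(v, cubic_roi(c(0, 0, 0), mask, half_width = 0L))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(gbar[1], gbar[2])      # bias decreases with series length
  expect_lt(gbar[2], 0.1)
})

test_that("roi_panel averages clusters and degenerates correctly", {
  tv <- two_region_volume(0.5, 0.7, d = c(6, 6, 2), n_vol = 128, seed = 14)
  mask <- tv$vol$mask
  suppressMessages({
    one <- roi_panel(list(tv$vol), matrix(c(2, 2, 1), 1), mask)
    two <- roi_panel(list(tv$vol), rbind(c(2, 2, 1), c(2, 2, 1)), mask)
  })
  for (mcol in c("alff", "falff", "lconn", "gconn"))
    expect_equal(two[[mcol]], one[[mcol]], tolerance = 1e-12)
})

test_that("ROI-mean H and ALFF are positively concordant across voxels", {
  # heterogeneous H across a small volume; per-voxel H vs ALFF
  d <- c(6, 6, 2); mask <- array(TRUE, d)
  set.seed(15)
  hmap <- array(stats::runif(prod(d), 0.3, 0.9), d)
  v <- simulate_volume(hmap, mask, 250, dt_study, seed = 16)
  X <- fractalbold:::mask_matrix(v)$X
  per_vox <- vapply(seq_len(ncol(X)), function(j) {
    s <- bold_series(X[, j], dt_study)
    c(hurst_psd(s)$hurst, alff(s))
  }, numeric(2))
  expect_gt(stats::cor(per_vox[1, ], per_vox[2, ], method = "spearman"), 0.2)
})
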