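#' Spectral density container
#'
#' @param freqs Strictly increasing frequencies in Hz, within (0, Nyquist].
#' @param power Non-negative power values, same length as `freqs`.
#' @param band_width Width in Hz of the integration bands (0 for a raw
#'   periodogram-resolution spectrum).
#' @return An object of class `spectral_density`.
#' @export
spectral_density <- function(freqs, power, band_width = 0) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (length(freqs) != length(power)) stop("freqs and power lengths differ")
  if (any(freqs <= 0)) stop("frequencies must be positive (DC excluded)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  if (any(power < 0)) stop("power must be non-negative")
  structure(list(freqs = freqs, power = power, band_width = band_width),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density> %d points, %.4g-%.4g Hz%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              if (x$band_width > 0) sprintf(", %g Hz bands", x$band_width) else ""))
  invisible(x)
}

# Welch PSD of every column of a matrix (one series per column).
# Hann taper, mean-removal per segment, one-sided density normalization:
# P(f) = 2 dt |sum w x e^{-i2pi f t}|^2 / sum(w^2), averaged over segments.
welch_psd_matrix <- function(X, dt, window_len = 64L, overlap_frac = 0.5) {
  n <- nrow(X)
  L <- as.integer(window_len)
  if (L < 8L) stop("'window_len' must be >= 8 samples")
  if (n < L) stop("series shorter than one window")
  hop <- max(1L, as.integer(round(L * (1 - overlap_frac))))
  starts <- seq.int(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))   # Hann
  U <- sum(w^2)
  nf <- L %/% 2L
  acc <- matrix(0, nf, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + L - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg)) * w
    F <- stats::mvfft(seg)
    P <- (Mod(F[2:(nf + 1L), , drop = FALSE])^2) * (2 * dt / U)
    if (L %% 2L == 0L) P[nf, ] <- P[nf, ] / 2   # Nyquist bin is not doubled
    acc <- acc + P
  }
  list(freqs = (1:nf) / (L * dt), power = acc / length(starts))
}

#' Welch power spectral density of a BOLD series
#'
#' Hann-tapered, 50%-overlapping segment-averaged periodogram in the density
#' convention (power per Hz, one-sided). Each segment has its mean removed
#' before tapering; the DC bin is excluded from the output.
#'
#' @param series A [bold_series()].
#' @param window_len Segment length in samples (default 64, about 136 s at
#'   TR 2.13 s, giving six segments from a 250-volume run).
#' @param overlap_frac Fractional overlap between consecutive segments.
#' @return A [spectral_density()] with `band_width = 0`.
#' @export
welch_psd <- function(series, window_len = 64L, overlap_frac = 0.5) {
  series <- as_bold_series(series)
  est <- welch_psd_matrix(matrix(series$values, ncol = 1L), series$dt,
                          window_len, overlap_frac)
  spectral_density(est$freqs, est$power[, 1L], band_width = 0)
}

#' Integrate a spectrum over contiguous frequency bands
#'
#' Sums power within contiguous bands of fixed width starting at 0 Hz
#' (bins assigned left-open/right-closed, so a bin at exactly a band edge
#' belongs to the lower band) and reports each band at its center frequency.
#' Total power is conserved over the covered range; bands containing no bins
#' are dropped. Band integration stabilizes the log-log power-law fit. The
#' number of bins per band is recorded in `n_bins` so downstream fits can
#' work with the band-mean density (bands need not cover equally many bins).
#'
#' @param psd A [spectral_density()].
#' @param band_width_hz Band width in Hz; must exceed the bin spacing.
#' @return A [spectral_density()] of band powers at band centers.
#' @export
integrate_bands <- function(psd, band_width_hz = 0.02) {
  stopifnot(inherits(psd, "spectral_density"))
  if (length(psd$freqs) > 1L) {
    res <- min(diff(psd$freqs))
    if (band_width_hz <= res + 1e-12)
      stop(sprintf("band width %.4g Hz is not wider than the bin spacing %.4g Hz",
                   band_width_hz, res))
  }
  idx <- ceiling(psd$freqs / band_width_hz - 1e-9)
  pw <- vapply(split(psd$power, idx), sum, numeric(1))
  nb <- vapply(split(psd$power, idx), length, integer(1))
  centers <- (as.numeric(names(pw)) - 0.5) * band_width_hz
  o <- order(centers)
  out <- spectral_density(centers[o], pw[o], band_width = band_width_hz)
  out$n_bins <- nb[o]   # bins per band, so fits can recover the mean density
  out
}

#' Map a spectral scaling exponent to a Hurst exponent
#'
#' Under a fractional Gaussian noise model, `PSD(f) = C |f|^-beta` implies
#' `H = (beta + 1) / 2`.
#'
#' @param beta Spectral slope exponent (negative log-log slope).
#' @return Hurst exponent(s).
#' @export
beta_to_hurst <- function(beta) (beta + 1) / 2

new_scaling_fit <- function(beta, hurst, log_c, r_squared, f_min, f_max,
                            model_ok, estimator, n_points) {
  structure(list(beta = beta, hurst = hurst, log_c = log_c,
                 r_squared = r_squared, f_min = f_min, f_max = f_max,
                 model_ok = model_ok, estimator = estimator,
                 n_points = n_points),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit:%s> H = %.3f (beta = %.3f), R^2 = %.3f, %s\n",
              x$estimator, x$hurst, x$beta, x$r_squared,
              if (isTRUE(x$model_ok)) "model ok" else "model check FAILED"))
  invisible(x)
}

#' Fit a power law to a (band-integrated) spectrum
#'
#' Ordinary least squares of `log(power)` on `log(freq)` over
#' `[f_min, f_max]`. The spectral exponent is `beta = -slope` and the Hurst
#' exponent `H = (beta + 1) / 2`. The fGn model check `model_ok` requires
#' `beta` in (-1, 1) (the stationary fGn regime) and `r_squared >= r2_min`
#' (linear goodness of fit); series failing it are flagged, not re-fit.
#'
#' @param psd A [spectral_density()], normally band-integrated.
#' @param f_min,f_max Fit range in Hz (defaults 0.015 and 0.225, the
#'   resting-state scaling band at TR 2.13 s).
#' @param r2_min Minimum R^2 for the model check (default 0.5).
#' @return A `scaling_fit` with elements `beta`, `hurst`, `log_c`,
#'   `r_squared`, `f_min`, `f_max`, `model_ok`.
#' @examples
#' psd <- spectral_density(seq(0.02, 0.22, 0.02), seq(0.02, 0.22, 0.02)^-0.8)
#' fit_powerlaw(psd)  # beta = 0.8, H = 0.9, R^2 = 1 exactly
#' @export
fit_powerlaw <- function(psd, f_min = 0.015, f_max = 0.225, r2_min = 0.5) {
  stopifnot(inherits(psd, "spectral_density"))
  if (f_min >= f_max) stop("'f_min' must be below 'f_max'")
  sel <- psd$freqs >= f_min & psd$freqs <= f_max
  f <- psd$freqs[sel]; p <- psd$power[sel]
  # band-integrated spectra carry bins-per-band: fit the mean density so
  # bands spanning unequal bin counts stay comparable on the log scale
  if (!is.null(psd$n_bins)) p <- p / psd$n_bins[sel]
  if (any(p <= 0)) {
    warning(sprintf("dropping %d non-positive power band(s) before log fit",
                    sum(p <= 0)))
    f <- f[p > 0]; p <- p[p > 0]
  }
  if (length(f) < 4L)
    stop(sprintf("only %d usable bands in [%g, %g] Hz; need >= 4",
                 length(f), f_min, f_max))
  lf <- log(f); lp <- log(p)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  slope <- fit$coefficients[[2L]]
  r2 <- 1 - sum(fit$residuals^2) / sum((lp - mean(lp))^2)
  if (!is.finite(r2)) r2 <- 1   # zero-variance log power: exact fit
  beta <- -slope
  new_scaling_fit(beta = beta, hurst = beta_to_hurst(beta),
                  log_c = fit$coefficients[[1L]], r_squared = r2,
                  f_min = f_min, f_max = f_max,
                  model_ok = beta > -1 && beta < 1 && r2 >= r2_min,
                  estimator = "psd", n_points = length(f))
}

#' PSD scaling estimate of a BOLD series
#'
#' Convenience wrapper chaining [welch_psd()], [integrate_bands()] and
#' [fit_powerlaw()] with the study defaults (Hann window of 64 samples, 50%
#' overlap, 0.02 Hz bands, fit over 0.015-0.225 Hz).
#'
#' @inheritParams welch_psd
#' @inheritParams fit_powerlaw
#' @param band_width_hz Band integration width in Hz.
#' @return A `scaling_fit`.
#' @export
hurst_psd <- function(series, window_len = 64L, overlap_frac = 0.5,
                      band_width_hz = 0.02, f_min = 0.015, f_max = 0.225,
                      r2_min = 0.5) {
  psd <- welch_psd(series, window_len, overlap_frac)
  fit_powerlaw(integrate_bands(psd, band_width_hz), f_min, f_max, r2_min)
}

#' Sensitivity of the power-law fit to the frequency bounds
#'
#' Refits the scaling exponent for every combination of candidate lower and
#' upper fit bounds, mirroring the robustness check of the scaling analysis
#' (lower bounds 0.015/0.02/0.025/0.03 Hz; upper bounds
#' 0.225/0.200/0.1875/0.175 Hz).
#'
#' @param series A [bold_series()] (or a [spectral_density()] already
#'   band-integrated).
#' @param lower_bounds,upper_bounds Candidate bounds in Hz.
#' @param ... Passed to [welch_psd()] / [integrate_bands()] when `series`
#'   is a time series.
#' @return A data.frame with one row per bound pair: `f_min`, `f_max`,
#'   `beta`, `hurst`, `r_squared`, `model_ok`.
#' @export
sensitivity_bounds <- function(series,
                               lower_bounds = c(0.015, 0.02, 0.025, 0.03),
                               upper_bounds = c(0.225, 0.200, 0.1875, 0.175),
                               ...) {
  if (any(outer(lower_bounds, upper_bounds, ">=")))
    stop("every lower bound must lie below every upper bound")
  psd <- if (inherits(series, "spectral_density")) series
         else integrate_bands(welch_psd(series, ...))
  grid <- expand.grid(f_min = lower_bounds, f_max = upper_bounds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ft <- fit_powerlaw(psd, grid$f_min[i], grid$f_max[i])
    data.frame(f_min = grid$f_min[i], f_max = grid$f_max[i], beta = ft$beta,
               hurst = ft$hurst, r_squared = ft$r_squared,
               model_ok = ft$model_ok)
  })
  do.call(rbind, rows)
}
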