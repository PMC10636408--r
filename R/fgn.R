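#' Closed-form autocovariance of fractional Gaussian noise
#'
#' The stationary autocovariance of fGn with Hurst exponent `H` and marginal
#' standard deviation `sigma`:
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)}
#' This is the exact target covariance of [simulate_fgn()] and serves as the
#' independent oracle in its tests.
#'
#' @param lag Integer lag(s), may be negative.
#' @param hurst Hurst exponent in (0, 1).
#' @param sigma Marginal standard deviation (> 0).
#' @return Numeric vector of autocovariances, one per lag.
#' @export
fgn_acov <- function(lag, hurst, sigma = 1) {
  stopifnot(hurst > 0, hurst < 1, sigma > 0)
  k <- abs(as.numeric(lag))
  sigma^2 / 2 * (abs(k + 1)^(2 * hurst) - 2 * k^(2 * hurst) + abs(k - 1)^(2 * hurst))
}

#' Specification of a fractional Gaussian noise series
#'
#' @param hurst Hurst exponent, in (0, 1).
#' @param sigma Marginal standard deviation, > 0.
#' @param n_samples Number of samples, >= 16.
#' @param dt Sampling interval in seconds, > 0 (the TR for BOLD data).
#' @return A validated `fgn_spec` object.
#' @export
fgn_spec <- function(hurst, sigma = 1, n_samples = 250, dt = 2.13) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly in (0, 1)")
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 16L) stop("'n_samples' must be >= 16")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0 seconds")
  structure(list(hurst = hurst, sigma = sigma, n_samples = n_samples, dt = dt),
            class = "fgn_spec")
}

# Eigenvalues of the circulant embedding of the fGn covariance, with
# next-power-of-two padding when the embedding is not positive semidefinite.
# Small negative eigenvalues (>= -tol * max) are clipped to zero.
fgn_circulant_eigen <- function(n, hurst, sigma = 1, tol = 1e-10) {
  m <- 2^ceiling(log2(max(n, 2)))
  repeat {
    g <- fgn_acov(0:m, hurst, sigma)
    row <- c(g, g[m:2])                      # circulant first row, length 2m
    ev <- Re(stats::fft(row))
    neg <- min(ev)
    if (neg >= -tol * max(ev)) {
      ev[ev < 0] <- 0
      return(ev)
    }
    message(sprintf(
      "circulant embedding not positive semidefinite at m = %d (min eig %.3g); padding to next power of two", m, neg))
    m <- 2L * m
  }
}

# Exact-in-distribution fGn draws, one series per column, sharing the current
# RNG stream. Davies-Harte: X = Re(F (sqrt(ev) xi)) / sqrt(N) with hermitian
# complex-Gaussian xi, so the n-sample covariance is exactly Toeplitz(gamma).
fgn_matrix <- function(n, hurst, n_series = 1L, sigma = 1) {
  ev <- fgn_circulant_eigen(n, hurst, sigma)
  N <- length(ev)
  m <- N %/% 2L
  Z <- matrix(stats::rnorm(N * n_series), N, n_series)
  xi <- matrix(0 + 0i, N, n_series)
  xi[1L, ] <- Z[1L, ]
  xi[m + 1L, ] <- Z[m + 1L, ]
  k <- 2:m
  xi[k, ] <- (Z[k, , drop = FALSE] + 1i * Z[N + 2L - k, , drop = FALSE]) / sqrt(2)
  xi[N + 2L - k, ] <- Conj(xi[k, , drop = FALSE])
  X <- Re(stats::mvfft(sqrt(ev) * xi)) / sqrt(N)
  X[seq_len(n), , drop = FALSE]
}

#' Simulate fractional Gaussian noise (exact circulant embedding)
#'
#' Draws a Gaussian series whose population autocovariance is exactly
#' [fgn_acov()] at every lag, via Davies-Harte circulant embedding. This is
#' exact-in-distribution (not an approximate filter); `H = 0.5` reduces to
#' i.i.d. white noise. If the embedding of the requested length is not
#' positive semidefinite it is padded to the next power of two, with a
#' diagnostic message.
#'
#' @param spec An [fgn_spec()] (or a Hurst exponent, with the remaining
#'   fields taken from `fgn_spec()` defaults).
#' @param seed Integer seed; the draw is a pure function of `(spec, seed)`.
#' @return A [bold_series()] of length `spec$n_samples`.
#' @examples
#' x <- simulate_fgn(fgn_spec(hurst = 0.7, n_samples = 256), seed = 1)
#' @export
simulate_fgn <- function(spec, seed) {
  if (is.numeric(spec)) spec <- fgn_spec(hurst = spec)
  stopifnot(inherits(spec, "fgn_spec"))
  set.seed(as.integer(seed))
  x <- fgn_matrix(spec$n_samples, spec$hurst, 1L, spec$sigma)[, 1L]
  bold_series(x, spec$dt)
}

#' Simulate a multifractal random walk (test oracle for multifractality)
#'
#' Increments \eqn{r_k = \epsilon_k e^{\omega_k}} with i.i.d. Gaussian
#' \eqn{\epsilon} and a Gaussian log-volatility \eqn{\omega} whose covariance
#' is \eqn{\lambda^2 \log^+(L/(|k|+1))}. The increment process has second
#' log-cumulant \eqn{c_2 = -\lambda^2}, which makes it the standard reference
#' signal for validating multifractal estimators (fGn, by contrast, has
#' \eqn{c_2 = 0}). The log-volatility is generated by circulant embedding
#' with negative-eigenvalue clipping (approximate, adequate for an oracle).
#'
#' @param n Number of increments.
#' @param lambda2 Intermittency parameter \eqn{\lambda^2 > 0}.
#' @param L Integral scale (correlation length) in samples; default `n / 2`.
#' @param dt Sampling interval in seconds.
#' @param seed Integer seed.
#' @return A [bold_series()] of `n` MRW increments.
#' @export
simulate_mrw <- function(n, lambda2 = 0.05, L = NULL, dt = 1, seed) {
  stopifnot(n >= 64, lambda2 > 0)
  if (is.null(L)) L <- n / 2
  set.seed(as.integer(seed))
  m <- 2^ceiling(log2(n))
  k <- 0:m
  g <- lambda2 * pmax(log(L / (k + 1)), 0)
  row <- c(g, g[m:2])
  ev <- Re(stats::fft(row))
  ev[ev < 0] <- 0                      # clipped embedding: oracle-grade only
  N <- length(ev)
  mm <- N %/% 2L
  Z <- stats::rnorm(N)
  xi <- complex(length.out = N)
  xi[1L] <- Z[1L]; xi[mm + 1L] <- Z[mm + 1L]
  kk <- 2:mm
  xi[kk] <- (Z[kk] + 1i * Z[N + 2L - kk]) / sqrt(2)
  xi[N + 2L - kk] <- Conj(xi[kk])
  omega <- Re(stats::fft(sqrt(ev) * xi)) / sqrt(N)
  omega <- omega[seq_len(n)]
  eps <- stats::rnorm(n)
  bold_series(eps * exp(omega - mean(omega)), dt)
}
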