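# Orthonormal Daubechies scaling filters (L2-normalized: sum h = sqrt(2)).
# db1 is Haar; dbN has N vanishing moments and 2N taps.
daubechies_filter <- function(wavelet = "db3") {
  h <- switch(tolower(wavelet),
    db1 = , haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604),
    db3 = c(0.3326705529500825, 0.8068915093110924, 0.4598775021184914,
            -0.1350110200102546, -0.0854412738820267, 0.0352262918857095),
    db4 = c(0.2303778133088964, 0.7148465705529154, 0.6308807679398587,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690),
    stop(sprintf("unknown wavelet '%s' (supported: haar/db1, db2, db3, db4)",
                 wavelet)))
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # quadrature mirror highpass
  list(h = h, g = g)
}

# Valid (boundary-free) convolution then dyadic downsampling.
conv_down <- function(x, f) {
  nf <- length(f)
  y <- stats::convolve(x, rev(f), type = "open")[nf:length(x)]
  y[seq.int(1L, length(y), by = 2L)]
}

# Pyramid DWT detail coefficients per octave j = 1..j_max, using only
# boundary-free coefficients (no periodic wrap-around), L2 normalization.
dwt_details <- function(x, wavelet = "db3", j_max = NULL) {
  flt <- daubechies_filter(wavelet)
  n <- length(x)
  if (is.null(j_max)) j_max <- max(1L, floor(log2(n)) - 3L)
  a <- x
  out <- vector("list", j_max)
  for (j in seq_len(j_max)) {
    if (length(a) < 2L * length(flt$h)) { out <- out[seq_len(j - 1L)]; break }
    out[[j]] <- conv_down(a, flt$g)
    a <- conv_down(a, flt$h)
  }
  out[lengths(out) > 0L]
}

#' Wavelet monofractal (log-scale diagram) scaling estimate
#'
#' Discrete wavelet transform of the series; per octave `j` the log2 of the
#' mean squared detail coefficient is bias-corrected (digamma correction for
#' the expectation of a log chi-square) and regressed on `j` with weights
#' inverse to the theoretical variance of the log energy. For stationary
#' fGn the slope is `2H - 1`, so `H = (slope + 1) / 2`.
#'
#' @param series A [bold_series()].
#' @param wavelet Wavelet name (`"db2"`, `"db3"` default, `"db4"`, `"haar"`).
#' @param j_min,j_max Octave range; defaults 2 and `floor(log2(n)) - 3`.
#' @return A `scaling_fit` with `estimator = "wma"`; `beta` is the fitted
#'   log-scale-diagram slope and `f_min`/`f_max` the frequency span
#'   `1/(2^j dt)` of the used octaves.
#' @export
wavelet_monofractal <- function(series, wavelet = "db3", j_min = 2L,
                                j_max = NULL) {
  series <- as_bold_series(series)
  n <- length(series$values)
  if (is.null(j_max)) j_max <- max(j_min, floor(log2(n)) - 3L)
  if (2^j_max > n / 2) stop("'j_max' too large: need 2^j_max <= n/2")
  det <- dwt_details(series$values, wavelet, j_max)
  js <- seq.int(j_min, min(j_max, length(det)))
  if (length(js) < 3L) stop("too few octaves (< 3) for a scaling fit")
  nj <- lengths(det[js])
  mu <- vapply(det[js], function(d) mean(d^2), numeric(1))
  if (any(mu <= 0)) stop("degenerate (all-zero) detail coefficients")
  yj <- log2(mu) - (digamma(nj / 2) / log(2) - log2(nj / 2))
  wj <- 1 / (trigamma(nj / 2) / log(2)^2)
  fit <- stats::lm.wfit(cbind(1, js), yj, wj)
  slope <- fit$coefficients[[2L]]
  r2 <- 1 - sum(wj * fit$residuals^2) /
    sum(wj * (yj - stats::weighted.mean(yj, wj))^2)
  new_scaling_fit(beta = slope, hurst = (slope + 1) / 2,
                  log_c = fit$coefficients[[1L]], r_squared = r2,
                  f_min = 1 / (2^max(js) * series$dt),
                  f_max = 1 / (2^min(js) * series$dt),
                  model_ok = slope > -1 && slope < 1 && r2 >= 0.5,
                  estimator = "wma", n_points = length(js))
}

#' Multifractal summary from wavelet-leader log-cumulants
#'
#' @param c1 First log-cumulant (self-similarity exponent; plays the role of
#'   `H` for monofractal signals under the integrated-path convention).
#' @param c2 Second log-cumulant (multifractality width; 0 for monofractal
#'   signals, negative for genuinely multifractal ones).
#' @param scale_range Integer vector of octaves used in the regression.
#' @param cumulants Per-octave cumulant table (for diagnostics).
#' @return An object of class `multifractal_summary`.
#' @export
multifractal_summary <- function(c1, c2, scale_range, cumulants = NULL) {
  stopifnot(is.finite(c1))
  structure(list(c1 = c1, c2 = c2, scale_range = scale_range,
                 cumulants = cumulants),
            class = "multifractal_summary")
}

#' @export
print.multifractal_summary <- function(x, ...) {
  cat(sprintf("<multifractal_summary> c1 = %.3f, c2 = %.3f (octaves %d-%d)\n",
              x$c1, x$c2, min(x$scale_range), max(x$scale_range)))
  invisible(x)
}

#' Wavelet-leader multifractal analysis (log-cumulants)
#'
#' Wavelet leaders are local suprema of L1-normalized wavelet coefficient
#' magnitudes over a three-cell dyadic neighborhood and all finer scales.
#' The first two cumulants of `log(leader)` are regressed on octave
#' (weights proportional to the coefficient count per octave); divided by
#' `log(2)` these give the log-cumulants `c1` (H-like exponent) and `c2`
#' (multifractality width, `-lambda^2` for a multifractal random walk, 0
#' for fGn). The series is integrated (cumulative sum) before analysis so
#' that a stationary noise-like input is analyzed through its motion-path
#' regularity and `c1` estimates `H` directly for fGn.
#'
#' @param series A [bold_series()].
#' @param wavelet Wavelet name (default `"db3"`).
#' @param j_min,j_max Octave range; defaults 2 and `floor(log2(n)) - 3`.
#' @param q_list Moment orders retained in the summary table (the cumulant
#'   method itself does not need them; default -2..2).
#' @param integrate Integrate the series before analysis (default `TRUE`).
#' @return A [multifractal_summary()].
#' @export
wavelet_leader_multifractal <- function(series, wavelet = "db3", j_min = 2L,
                                        j_max = NULL, q_list = -2:2,
                                        integrate = TRUE) {
  series <- as_bold_series(series)
  x <- series$values
  if (stats::sd(x) == 0) stop("degenerate (constant) signal: leaders undefined")
  if (integrate) x <- cumsum(x - mean(x))
  n <- length(x)
  if (is.null(j_max)) j_max <- max(j_min, floor(log2(n)) - 3L)
  det <- dwt_details(x, wavelet, j_max)
  # L1-normalized magnitudes: |d_{j,k}| 2^{-j/2}
  mags <- lapply(seq_along(det), function(j) abs(det[[j]]) * 2^(-j / 2))
  # sup over all finer scales within each dyadic cell, then 3-neighborhood
  acc <- mags[[1L]]
  leaders <- vector("list", length(mags))
  for (j in seq_along(mags)) {
    if (j > 1L) {
      k <- length(mags[[j]])
      child <- matrix(acc[seq_len(2L * k)], nrow = 2L)
      acc <- pmax(mags[[j]], apply(child, 2L, max))
    }
    L <- length(acc)
    leaders[[j]] <- pmax(acc,
                         c(acc[1L], acc[-L]),      # left neighbor
                         c(acc[-1L], acc[L]))      # right neighbor
  }
  js <- seq.int(j_min, length(leaders))
  js <- js[lengths(leaders[js]) >= 4L]
  if (length(js) < 3L) stop("leaders require >= 3 usable octaves")
  lead <- leaders[js]
  if (any(vapply(lead, function(l) any(l <= 0), logical(1))))
    stop("degenerate leaders (zero suprema)")
  C1 <- vapply(lead, function(l) mean(log(l)), numeric(1))
  C2 <- vapply(lead, function(l) mean((log(l) - mean(log(l)))^2), numeric(1))
  nj <- lengths(lead)
  w <- nj
  wfit <- function(y) stats::lm.wfit(cbind(1, js), y, w)$coefficients[[2L]]
  c1 <- wfit(C1) / log(2)
  c2 <- wfit(C2) / log(2)
  zq <- vapply(q_list, function(q) {
    Sq <- vapply(lead, function(l) mean(l^q), numeric(1))
    wfit(log2(Sq))
  }, numeric(1))
  out <- multifractal_summary(c1 = c1, c2 = c2, scale_range = js,
                              cumulants = data.frame(j = js, n = nj,
                                                     C1 = C1, C2 = C2))
  out$zeta_q <- stats::setNames(zq, paste0("q", q_list))
  out
}
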