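#' Detrended fluctuation analysis
#'
#' The series is integrated into a cumulative-sum profile, divided into
#' non-overlapping boxes of size `s` (taken from both ends of the record so
#' trailing samples are used), each box is detrended with a polynomial of
#' order `detrend_order`, and the RMS residual fluctuation `F(s)` is
#' regressed on `s` in log-log coordinates across a log-spaced grid of box
#' sizes. For fractional Gaussian noise the slope estimates the Hurst
#' exponent directly; order-1 detrending makes the estimate immune to linear
#' trends in the raw series.
#'
#' @param series A [bold_series()].
#' @param min_box,max_box Smallest and largest box sizes in samples
#'   (defaults 8 and `n / 4`).
#' @param n_boxes Number of log-spaced box sizes (default 10).
#' @param detrend_order Polynomial detrending order (default 1).
#' @return A `scaling_fit` with `estimator = "dfa"`; `hurst` is the log-log
#'   slope, `beta = 2 * hurst - 1` under the fGn correspondence, and
#'   `f_min`/`f_max` are the frequencies 1/(s_max dt), 1/(s_min dt) spanned
#'   by the box grid.
#' @export
dfa <- function(series, min_box = 8L, max_box = NULL, n_boxes = 10L,
                detrend_order = 1L) {
  series <- as_bold_series(series)
  x <- series$values
  n <- length(x)
  if (is.null(max_box)) max_box <- floor(n / 4)
  min_box <- as.integer(min_box); max_box <- as.integer(max_box)
  if (n < 4L * min_box)
    stop(sprintf("series length %d below 4 * min_box = %d", n, 4L * min_box))
  if (max_box <= min_box || max_box > n %/% 2L)
    stop("infeasible box grid: need min_box < max_box <= n/2")
  sizes <- unique(round(exp(seq(log(min_box), log(max_box),
                                length.out = n_boxes))))
  sizes <- sizes[sizes >= detrend_order + 2L]
  if (length(sizes) < 4L) stop("box grid infeasible: fewer than 4 distinct sizes")
  prof <- cumsum(x - mean(x))
  Fs <- vapply(sizes, function(s) {
    nb <- n %/% s
    idx <- c(seq_len(nb * s), (n - nb * s + 1L):n)   # forward + backward cover
    seg <- matrix(prof[idx], nrow = s)
    tt <- stats::poly(seq_len(s), degree = detrend_order, raw = FALSE)
    T <- cbind(1, tt)
    res <- seg - T %*% solve(crossprod(T), crossprod(T, seg))
    sqrt(mean(res^2))
  }, numeric(1))
  ls <- log(sizes); lF <- log(Fs)
  fit <- stats::lm.fit(cbind(1, ls), lF)
  slope <- fit$coefficients[[2L]]
  r2 <- 1 - sum(fit$residuals^2) / sum((lF - mean(lF))^2)
  new_scaling_fit(beta = 2 * slope - 1, hurst = slope,
                  log_c = fit$coefficients[[1L]], r_squared = r2,
                  f_min = 1 / (max(sizes) * series$dt),
                  f_max = 1 / (min(sizes) * series$dt),
                  model_ok = slope > 0 && slope < 1.5 && r2 >= 0.9,
                  estimator = "dfa", n_points = length(sizes))
}
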