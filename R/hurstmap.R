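#' Voxelwise Hurst-exponent map of a 4D volume
#'
#' Applies a scaling estimator independently to every in-mask voxel time
#' series. The PSD route is fully vectorized (one Welch spectrum per voxel,
#' shared band grid, closed-form per-voxel OLS); DFA, wavelet monofractal
#' and wavelet-leader estimators loop over voxels. Per-voxel fit diagnostics
#' (R^2 and the fGn model check) are carried in the map; voxels whose fit
#' fails are set to `NaN` and counted.
#'
#' @param vol A [volume_set()].
#' @param estimator One of `"psd"`, `"dfa"`, `"wma"`, `"wlm"`.
#' @param ... Estimator parameters passed through ([hurst_psd()], [dfa()],
#'   [wavelet_monofractal()], [wavelet_leader_multifractal()]).
#' @return A `hurst_map`: list with 3D arrays `hurst`, `r_squared`,
#'   `model_ok` (NaN/NA outside mask), the `mask`, `estimator`,
#'   `voxel_size`, and `n_failed`.
#' @export
hurst_volume <- function(vol, estimator = c("psd", "dfa", "wma", "wlm"), ...) {
  stopifnot(inherits(vol, "volume_set"))
  estimator <- match.arg(estimator)
  mm <- mask_matrix(vol)
  if (length(mm$idx) == 0L) stop("mask is empty")
  nv <- length(mm$idx)
  hv <- rep(NaN, nv); r2v <- rep(NaN, nv); okv <- rep(NA, nv)
  if (estimator == "psd") {
    est <- psd_fit_matrix(mm$X, vol$tr, ...)
    hv <- est$hurst; r2v <- est$r_squared; okv <- est$model_ok
  } else {
    fun <- switch(estimator, dfa = dfa, wma = wavelet_monofractal,
                  wlm = wavelet_leader_multifractal)
    for (i in seq_len(nv)) {
      ft <- tryCatch(fun(bold_series(mm$X[, i], vol$tr), ...),
                     error = function(e) NULL)
      if (is.null(ft)) next
      if (estimator == "wlm") {
        hv[i] <- ft$c1; r2v[i] <- NA_real_; okv[i] <- TRUE
      } else {
        hv[i] <- ft$hurst; r2v[i] <- ft$r_squared; okv[i] <- ft$model_ok
      }
    }
  }
  n_failed <- sum(!is.finite(hv))
  if (n_failed > 0L)
    message(sprintf("hurst_volume: %d of %d voxel fits failed (NaN)", n_failed, nv))
  blank <- array(NaN, dim(vol$mask))
  H <- blank; H[mm$idx] <- hv
  R2 <- blank; R2[mm$idx] <- r2v
  OK <- array(NA, dim(vol$mask)); OK[mm$idx] <- okv
  structure(list(hurst = H, r_squared = R2, model_ok = OK, mask = vol$mask,
                 estimator = estimator, voxel_size = vol$voxel_size,
                 n_failed = n_failed),
            class = "hurst_map")
}

# Vectorized Welch + band-integrated power-law fit for a time-by-voxel
# matrix; same conventions as hurst_psd().
psd_fit_matrix <- function(X, dt, window_len = 64L, overlap_frac = 0.5,
                           band_width_hz = 0.02, f_min = 0.015,
                           f_max = 0.225, r2_min = 0.5) {
  est <- welch_psd_matrix(X, dt, window_len, overlap_frac)
  bidx <- ceiling(est$freqs / band_width_hz - 1e-9)
  P <- rowsum(est$power, bidx)                       # bands x voxels
  P <- P / as.vector(table(bidx))                    # mean density per band
  ctr <- (as.numeric(rownames(P)) - 0.5) * band_width_hz
  sel <- ctr >= f_min & ctr <= f_max
  P <- P[sel, , drop = FALSE]; ctr <- ctr[sel]
  if (length(ctr) < 4L) stop("fewer than 4 bands in the fit range")
  lf <- log(ctr)
  ok_p <- P > 0
  usable <- colSums(ok_p) >= 4L
  lp <- log(pmax(P, .Machine$double.xmin))
  lp[!ok_p] <- 0                      # dropped bands contribute nothing below
  # closed-form OLS per column, tolerating per-voxel dropped bands
  nb <- colSums(ok_p)
  sx <- colSums(lf * ok_p); sxx <- colSums(lf^2 * ok_p)
  sy <- colSums(lp)
  sxy <- colSums(lf * lp)
  syy <- colSums(lp^2)
  vx <- sxx - sx^2 / nb
  slope <- (sxy - sx * sy / nb) / vx
  sse <- syy - sy^2 / nb - slope^2 * vx
  sst <- syy - sy^2 / nb
  r2 <- ifelse(sst > 0, 1 - sse / sst, 1)
  r2 <- pmin(pmax(r2, 0), 1)
  beta <- -slope
  hurst <- beta_to_hurst(beta)
  hurst[!usable] <- NaN
  list(hurst = hurst, beta = beta, r_squared = r2,
       model_ok = usable & beta > -1 & beta < 1 & r2 >= r2_min)
}

#' @export
print.hurst_map <- function(x, ...) {
  v <- x$hurst[x$mask]
  cat(sprintf("<hurst_map:%s> %d mask voxels, mean H = %.3f, %d failed, %d model-flagged\n",
              x$estimator, sum(x$mask), mean(v, na.rm = TRUE), x$n_failed,
              sum(!x$model_ok[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Global Hurst exponent of a map
#'
#' The mean over all valid (finite) in-mask voxel H values — the per-
#' participant gray-matter average used in group comparisons of global
#' scaling behavior.
#'
#' @param map A `hurst_map` from [hurst_volume()], or a 3D array paired
#'   with `mask`.
#' @param mask Optional 3D logical mask when `map` is a bare array.
#' @return Scalar mean H.
#' @export
global_hurst <- function(map, mask = NULL) {
  if (inherits(map, "hurst_map")) { mask <- map$mask; map <- map$hurst }
  if (is.null(mask)) stop("a mask is required")
  v <- map[mask]
  good <- is.finite(v)
  if (!any(good)) stop("no valid in-mask voxels")
  if (any(!good))
    message(sprintf("global_hurst: averaging %d of %d voxels (%d invalid)",
                    sum(good), length(v), sum(!good)))
  mean(v[good])
}
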