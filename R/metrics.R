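#' Cubic region of interest on a voxel grid
#'
#' A cube of half-width `half_width` voxels centered on a grid voxel
#' (half-width 1 gives the 27-voxel cube used for cluster ROIs), clipped to
#' the grid and intersected with the analysis mask.
#'
#' @param center_voxel 0-based (x, y, z) grid indices of the cube center.
#' @param mask 3D logical array; ROI voxels outside it are dropped.
#' @param half_width Half-width in voxels (default 1).
#' @return A `cubic_roi`: list with `center_voxel`, `half_width`,
#'   `member_voxels` (linear indices into the grid) and `n_requested`.
#' @export
cubic_roi <- function(center_voxel, mask, half_width = 1L) {
  stopifnot(length(center_voxel) == 3L, length(dim(mask)) == 3L)
  d <- dim(mask)
  c1 <- as.integer(center_voxel) + 1L      # to 1-based
  rng <- lapply(1:3, function(a)
    max(1L, c1[a] - half_width):min(d[a], c1[a] + half_width))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  lin <- g[, 1] + (g[, 2] - 1L) * d[1] + (g[, 3] - 1L) * d[1] * d[2]
  member <- lin[mask[lin]]
  if (length(member) < 1L) stop("ROI has no voxels after mask intersection")
  structure(list(center_voxel = as.integer(center_voxel),
                 half_width = as.integer(half_width),
                 member_voxels = member, n_requested = nrow(g)),
            class = "cubic_roi")
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Total BOLD power summed over 0.015-0.08 Hz, computed from the same
#' band-integrated Welch PSD as the scaling analysis. Scales with the square
#' of signal amplitude and is invariant to constant offsets.
#'
#' @param series A [bold_series()].
#' @param f_low,f_high Band limits in Hz.
#' @param window_len,overlap_frac,band_width_hz Welch/band parameters as in
#'   [hurst_psd()].
#' @return Scalar power sum (PSD units).
#' @export
alff <- function(series, f_low = 0.015, f_high = 0.08, window_len = 64L,
                 overlap_frac = 0.5, band_width_hz = 0.02) {
  psd <- integrate_bands(welch_psd(series, window_len, overlap_frac),
                         band_width_hz)
  sel <- psd$freqs >= f_low & psd$freqs <= f_high
  if (!any(sel)) stop("no bands inside the ALFF range")
  sum(psd$power[sel])
}

#' Fractional ALFF
#'
#' [alff()] normalized by the total band power over (0, Nyquist]; lies in
#' `[0, 1]` and is invariant to amplitude scaling.
#'
#' @inheritParams alff
#' @return Scalar in `[0, 1]`.
#' @export
falff <- function(series, f_low = 0.015, f_high = 0.08, window_len = 64L,
                  overlap_frac = 0.5, band_width_hz = 0.02) {
  psd <- integrate_bands(welch_psd(series, window_len, overlap_frac),
                         band_width_hz)
  tot <- sum(psd$power)
  if (tot <= 0) stop("zero total power (constant series?)")
  sel <- psd$freqs >= f_low & psd$freqs <= f_high
  if (!any(sel)) stop("no bands inside the ALFF range")
  sum(psd$power[sel]) / tot
}

# In-mask series matrix for a set of linear voxel indices.
roi_series <- function(vol, voxels) {
  nt <- dim(vol$data)[4L]
  m <- matrix(vol$data, ncol = nt)       # voxel x time
  t(m[voxels, , drop = FALSE])
}

#' Local connectivity of a cubic ROI
#'
#' Mean pairwise Pearson correlation over all unordered distinct voxel
#' pairs within the ROI (diagonal excluded). Constant voxel series, whose
#' correlation is undefined, are excluded with a message.
#'
#' @param vol A [volume_set()].
#' @param roi A [cubic_roi()].
#' @return Scalar mean correlation in `[-1, 1]`.
#' @export
local_connectivity <- function(vol, roi) {
  X <- roi_series(vol, roi$member_voxels)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("local_connectivity: excluding %d constant voxel series",
                    sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need >= 2 non-constant ROI voxels")
  R <- stats::cor(X)
  mean(R[upper.tri(R)])
}

#' Global connectivity of a cubic ROI
#'
#' Pearson correlation of the ROI mean time series with every other in-mask
#' voxel, averaged as a mean absolute correlation. The ROI's own voxels are
#' excluded from the target set.
#'
#' @param vol A [volume_set()].
#' @param roi A [cubic_roi()].
#' @param mask Optional mask (defaults to the volume's mask).
#' @return Scalar in `[0, 1]`.
#' @export
global_connectivity <- function(vol, roi, mask = NULL) {
  if (is.null(mask)) mask <- vol$mask
  targets <- setdiff(which(mask), roi$member_voxels)
  if (length(targets) == 0L) stop("mask minus ROI is empty")
  ref <- rowMeans(roi_series(vol, roi$member_voxels))
  X <- roi_series(vol, targets)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("global_connectivity: excluding %d constant voxel series",
                    sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (stats::sd(ref) == 0) stop("constant ROI mean series")
  mean(abs(stats::cor(ref, X)))
}

#' Per-participant ROI metric panel
#'
#' For each participant, computes (ALFF, fALFF, Lconn, Gconn) on a cubic
#' ROI at each supplied cluster center of mass, then averages across
#' clusters, yielding one row of metrics per participant. Effective ROI
#' sizes after mask intersection are reported via message.
#'
#' @param volumes List of [volume_set()]s, one per participant.
#' @param cluster_centers Matrix (or data.frame) of 0-based voxel grid
#'   coordinates, one row per cluster center.
#' @param mask Optional shared mask (defaults to each volume's own).
#' @param half_width ROI half-width in voxels (default 1: 27 voxels).
#' @param ids Optional participant identifiers.
#' @return data.frame with columns `participant`, `alff`, `falff`, `lconn`,
#'   `gconn`.
#' @export
roi_panel <- function(volumes, cluster_centers, mask = NULL, half_width = 1L,
                      ids = NULL) {
  cluster_centers <- as.matrix(cluster_centers)
  if (ncol(cluster_centers) != 3L) stop("cluster_centers must be n x 3")
  if (is.null(ids)) ids <- seq_along(volumes)
  m0 <- if (is.null(mask)) volumes[[1L]]$mask else mask
  rois <- apply(cluster_centers, 1L, function(ctr) cubic_roi(ctr, m0, half_width),
                simplify = FALSE)
  message(sprintf("roi_panel: %d ROI(s), effective sizes %s",
                  length(rois),
                  paste(vapply(rois, function(r) length(r$member_voxels), 1L),
                        collapse = "/")))
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    per <- vapply(rois, function(r) {
      mseries <- bold_series(rowMeans(roi_series(v, r$member_voxels)), v$tr)
      c(alff = alff(mseries), falff = falff(mseries),
        lconn = local_connectivity(v, r),
        gconn = global_connectivity(v, r, m0))
    }, numeric(4))
    data.frame(participant = ids[i], t(rowMeans(per)))
  })
  do.call(rbind, rows)
}
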