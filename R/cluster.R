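# Gaussian smoothing of a 3D array (zero-padded FFT convolution).
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  sd_vox <- (fwhm_mm / sqrt(8 * log(2))) / voxel_size
  if (all(sd_vox <= 0)) return(arr)
  half <- pmax(1L, ceiling(3 * sd_vox))
  k1 <- lapply(1:3, function(ax) {
    if (sd_vox[ax] <= 0) return(1)
    k <- stats::dnorm(-half[ax]:half[ax], sd = sd_vox[ax])
    k / sum(k)
  })
  half <- vapply(k1, function(k) (length(k) - 1L) %/% 2L, integer(1))
  d <- dim(arr)
  dp <- d + 2L * half
  A <- array(0, dp)
  A[half[1] + seq_len(d[1]), half[2] + seq_len(d[2]), half[3] + seq_len(d[3])] <- arr
  K <- array(0, dp)
  K[seq_along(k1[[1]]), seq_along(k1[[2]]), seq_along(k1[[3]])] <-
    outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(dp)
  sh <- 2L * half  # linear convolution offset to the kernel center
  out[sh[1] + seq_len(d[1]), sh[2] + seq_len(d[2]), sh[3] + seq_len(d[3]),
      drop = FALSE]
}

#' Spatial smoothness (Gaussian FWHM) of residual maps
#'
#' Classic variance-of-differences estimator: per axis, the lag-1 spatial
#' autocorrelation of the standardized residuals is computed from adjacent
#' in-mask voxel pairs, and mapped to the FWHM of the Gaussian kernel that
#' would produce it, `FWHM = dx * sqrt(-2 log 2 / log(rho1))`. Estimates
#' are averaged over maps and floored at the voxel size (data smoother than
#' a single voxel cannot be resolved; unsmoothed noise reports the floor).
#'
#' @param resid_maps A list of 3D arrays (per-participant residual maps)
#'   or a single 3D array.
#' @param mask 3D logical mask.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return Numeric length-3 vector of FWHM in mm per axis, with attribute
#'   `mean` (geometric mean across axes).
#' @export
estimate_smoothness <- function(resid_maps, mask, voxel_size = 3) {
  if (!is.list(resid_maps)) resid_maps <- list(resid_maps)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (sum(mask) < 100L)
    warning("mask has fewer than 100 voxels; smoothness estimate is unstable")
  d <- dim(mask)
  slab <- function(z, ax, drop_last) {
    ii <- lapply(d, seq_len)
    ii[[ax]] <- if (drop_last) 1:(d[ax] - 1L) else 2:d[ax]
    do.call(`[`, c(list(z), ii, list(drop = FALSE)))
  }
  per_map <- vapply(resid_maps, function(m) {
    v <- m[mask]
    if (stats::sd(v) == 0) stop("constant residual map: smoothness undefined")
    z <- array(NA_real_, d); z[mask] <- (v - mean(v)) / stats::sd(v)
    vapply(1:3, function(ax) {
      a <- slab(z, ax, TRUE); b <- slab(z, ax, FALSE)
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 10L) return(voxel_size[ax])
      rho <- 1 - mean((a[ok] - b[ok])^2) / 2
      if (rho <= 0 || rho >= 1) return(voxel_size[ax])
      max(voxel_size[ax], voxel_size[ax] * sqrt(-2 * log(2) / log(rho)))
    }, numeric(1))
  }, numeric(3))
  fwhm <- rowMeans(per_map)
  names(fwhm) <- c("x", "y", "z")
  attr(fwhm, "mean") <- exp(mean(log(fwhm)))
  fwhm
}

# Neighbor offsets for face (6), face+edge (18) or full (26) connectivity.
connectivity_offsets <- function(connectivity = 18L) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1L,
                 "18" = rowSums(abs(g)) <= 2L,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Flood-fill labelling under 6-, 18- (default, faces + edges) or
#' 26-connectivity.
#'
#' @param supra 3D logical array of suprathreshold voxels.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array of component labels (0 = background).
#' @export
label_clusters <- function(supra, connectivity = 18L) {
  d <- dim(supra)
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(supra)
  if (length(idx) == 0L) return(labels)
  coords <- arrayInd(idx, d)
  lab <- 0L
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    lab <- lab + 1L
    stack <- matrix(coords[s, ], ncol = 3L)
    labels[idx[s]] <- lab
    while (nrow(stack) > 0L) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      nb <- sweep(off, 2L, cur, `+`)
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[supra[lin] & labels[lin] == 0L]
      if (length(new) > 0L) {
        labels[new] <- lab
        stack <- rbind(stack, arrayInd(new, d))
      }
    }
  }
  labels
}

# Max cluster size of |z| >= zcrit in one simulated smooth null field.
null_max_cluster <- function(d, mask_idx, zcrit, kernel_fwhm, voxel_size,
                             connectivity) {
  x <- array(stats::rnorm(prod(d)), d)
  if (any(kernel_fwhm > voxel_size))
    x <- gaussian_smooth_3d(x, kernel_fwhm, voxel_size)
  v <- x[mask_idx]
  z <- (v - mean(v)) / stats::sd(v)
  supra <- array(FALSE, d)
  supra[mask_idx[abs(z) >= zcrit]] <- TRUE
  if (!any(supra)) return(0L)
  max(tabulate(label_clusters(supra, connectivity)))
}

#' Monte-Carlo cluster-size threshold and cluster report
#'
#' Simulates `n_sim` Gaussian null fields with the supplied spatial
#' smoothness inside the mask, thresholds each at the two-tailed voxelwise
#' level `p_voxel`, and records the maximum cluster size. The minimum
#' cluster size is the smallest integer whose null exceedance probability
#' is at most `alpha` (familywise control of any-cluster false positives).
#' Observed suprathreshold clusters at least that large are reported with
#' volume in mm^3, center of mass in mm (via the affine), peak BSR and an
#' optional atlas label.
#'
#' @param p_map 3D array of two-tailed voxelwise p-values.
#' @param mask 3D logical mask.
#' @param p_voxel Voxelwise (cluster-forming) threshold, default 0.005.
#' @param alpha Cluster-level familywise level, default 0.05.
#' @param fwhm_mm Spatial smoothness (length 1 or 3) from
#'   [estimate_smoothness()]; values below the voxel size are treated as
#'   unsmoothed.
#' @param n_sim Number of null simulations (default 2000).
#' @param seed Integer seed.
#' @param voxel_size Voxel edge lengths in mm.
#' @param bsr_map Optional BSR array for peak reporting.
#' @param connectivity Cluster-forming connectivity (default 18).
#' @param label_volume,label_table Optional integer atlas volume and
#'   data.frame with columns `id`, `label` for region naming at the CoM.
#' @return List with `min_cluster_size`, `null_max_sizes`, and `clusters`
#'   (data.frame: size, volume_mm3, com_x/y/z mm, peak_bsr, label).
#' @export
cluster_threshold <- function(p_map, mask, p_voxel = 0.005, alpha = 0.05,
                              fwhm_mm, n_sim = 2000L, seed, voxel_size = 3,
                              bsr_map = NULL, connectivity = 18L,
                              label_volume = NULL, label_table = NULL) {
  d <- dim(mask)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  fwhm_mm <- pmax(fwhm_mm, 0)
  mask_idx <- which(mask)
  zcrit <- stats::qnorm(1 - p_voxel / 2)
  set.seed(as.integer(seed))
  ms <- vapply(seq_len(n_sim), function(i)
    null_max_cluster(d, mask_idx, zcrit, fwhm_mm, voxel_size, connectivity),
    integer(1))
  # smallest k with P(max cluster >= k) <= alpha
  k <- 1L
  while (mean(ms >= k) > alpha) k <- k + 1L
  supra <- array(FALSE, d)
  supra[mask_idx[p_map[mask_idx] < p_voxel]] <- TRUE
  labels <- label_clusters(supra, connectivity)
  sizes <- tabulate(labels)
  keep <- which(sizes >= k)
  rows <- lapply(keep, function(cl) {
    vox <- which(labels == cl)
    co <- arrayInd(vox, d) - 1L           # 0-based voxel coordinates
    com <- colMeans(co) * voxel_size
    peak <- if (is.null(bsr_map)) NA_real_ else {
      b <- bsr_map[vox]; b[which.max(abs(b))]
    }
    lab <- NA_character_
    if (!is.null(label_volume) && !is.null(label_table)) {
      com_vox <- round(colMeans(co)) + 1L
      id <- label_volume[com_vox[1], com_vox[2], com_vox[3]]
      hit <- match(id, label_table$id)
      if (!is.na(hit)) lab <- as.character(label_table$label[hit])
    }
    data.frame(size = sizes[cl], volume_mm3 = sizes[cl] * prod(voxel_size),
               com_x = com[1], com_y = com[2], com_z = com[3],
               peak_bsr = peak, label = lab)
  })
  clusters <- if (length(rows) > 0L) do.call(rbind, rows)
    else data.frame(size = integer(), volume_mm3 = numeric(),
                    com_x = numeric(), com_y = numeric(), com_z = numeric(),
                    peak_bsr = numeric(), label = character())
  if (nrow(clusters) > 0L)
    clusters <- clusters[order(-clusters$volume_mm3), , drop = FALSE]
  list(min_cluster_size = k, null_max_sizes = ms, clusters = clusters,
       cluster_labels = labels, p_voxel = p_voxel, alpha = alpha)
}
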