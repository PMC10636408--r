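#' 4D BOLD volume with mask and geometry
#'
#' The per-participant imaging unit: a 4D data grid (x, y, z, time), a 3D
#' logical gray-matter mask, the voxel size in mm (encoded in the affine)
#' and the repetition time in seconds.
#'
#' @param data 4D numeric array (nx, ny, nz, nt).
#' @param mask 3D logical array matching the spatial grid.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param tr Repetition time in seconds.
#' @return An object of class `volume_set` with a diagonal `affine`
#'   (voxel index, 0-based, to mm).
#' @export
volume_set <- function(data, mask, voxel_size = 3, tr = 2.13) {
  stopifnot(length(dim(data)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(data)[1:3] == dim(mask)))
    stop("spatial dimensions of 'data' and 'mask' differ")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  affine <- diag(c(voxel_size, 1))
  structure(list(data = data, mask = array(as.logical(mask), dim(mask)),
                 voxel_size = voxel_size, tr = tr, affine = affine),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_set> %dx%dx%d grid, %d volumes, %d mask voxels, %g mm, TR %g s\n",
              d[1], d[2], d[3], d[4], sum(x$mask), x$voxel_size[1], x$tr))
  invisible(x)
}

# In-mask time-by-voxel matrix and the mask's linear indices.
mask_matrix <- function(vol) {
  idx <- which(vol$mask)
  nt <- dim(vol$data)[4L]
  m <- matrix(aperm(vol$data, c(4L, 1L, 2L, 3L)), nrow = nt)
  list(X = m[, idx, drop = FALSE], idx = idx)
}

#' Simulate a 4D volume of voxelwise fractional Gaussian noise
#'
#' Every in-mask voxel receives an independent exact fGn series with the
#' Hurst exponent given by `h_map` at that voxel; out-of-mask voxels are
#' zero. Voxels are spatially independent by construction, so the ground
#' truth H of each voxel is exactly the map value. An optional Gaussian
#' spatial smoothing step (applied frame by frame) is available solely to
#' give the data a controlled spatial smoothness for cluster-threshold
#' calibration; it mildly biases per-voxel H toward the neighborhood
#' average and is off by default.
#'
#' @param h_map 3D array of Hurst exponents (values in (0,1) inside mask).
#' @param mask 3D logical array.
#' @param n_volumes Number of time points.
#' @param tr Repetition time, seconds.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param sigma Marginal SD of each voxel series.
#' @param voxel_size Voxel size in mm.
#' @param smooth_fwhm_mm Optional spatial Gaussian FWHM in mm (0 = none).
#' @return A [volume_set()].
#' @export
simulate_volume <- function(h_map, mask, n_volumes = 250L, tr = 2.13, seed,
                            sigma = 1, voxel_size = 3, smooth_fwhm_mm = 0) {
  if (!all(dim(h_map) == dim(mask)))
    stop("shape mismatch between 'h_map' and 'mask'")
  mask <- array(as.logical(mask), dim(mask))
  idx <- which(mask)
  hv <- h_map[idx]
  if (length(idx) == 0L) {
    warning("empty mask: returning an all-zero volume")
    return(volume_set(array(0, c(dim(mask), n_volumes)), mask, voxel_size, tr))
  }
  if (any(!is.finite(hv)) || any(hv <= 0) || any(hv >= 1))
    stop("h_map values inside the mask must lie in (0, 1)")
  set.seed(as.integer(seed))
  tv <- matrix(0, n_volumes, length(idx))
  # one generator call per distinct H keeps the eigenvalue FFT shared
  for (h in sort(unique(hv))) {
    cols <- which(hv == h)
    tv[, cols] <- fgn_matrix(n_volumes, h, length(cols), sigma)
  }
  if (smooth_fwhm_mm > 0) {
    vs <- if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size
    full <- array(0, dim(mask))
    for (t in seq_len(n_volumes)) {
      full[idx] <- tv[t, ]
      tv[t, ] <- gaussian_smooth_3d(full, smooth_fwhm_mm, vs)[idx]
    }
  }
  flat <- matrix(0, n_volumes, prod(dim(mask)))
  flat[, idx] <- tv
  volume_set(array(t(flat), c(dim(mask), n_volumes)), mask, voxel_size, tr)
}

# Write a 3D/4D array as NIfTI-1 with the package's diagonal geometry.
write_nifti_vol <- function(arr, path, voxel_size = 3, tr = NULL) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  pix <- if (length(dim(arr)) == 4L && !is.null(tr)) c(voxel_size, tr) else voxel_size
  img <- RNifti::asNifti(arr, pixdim = pix)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
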