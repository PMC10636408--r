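GROUP_LEVELS <- c("control", "covid_h_minus", "covid_h_plus", "covid_h_r")

#' GLM design matrix for group comparisons
#'
#' Intercept; three binary indicators for the COVID subgroups (controls are
#' the reference level); age centered at the sample mean; sex coded {0, 1}.
#'
#' @param table data.frame with columns `group` (levels control,
#'   covid_h_minus, covid_h_plus, covid_h_r), `age` (years) and `sex` (0/1).
#' @return Numeric matrix with named columns and attributes `group`
#'   (factor) used for bootstrap stratification checks.
#' @export
make_design <- function(table) {
  g <- factor(table$group, levels = GROUP_LEVELS)
  if (anyNA(g)) stop("unknown group label(s) in 'group'")
  X <- cbind(intercept = 1,
             covid_h_minus = as.numeric(g == "covid_h_minus"),
             covid_h_plus = as.numeric(g == "covid_h_plus"),
             covid_h_r = as.numeric(g == "covid_h_r"),
             age = as.numeric(table$age) - mean(as.numeric(table$age)),
             sex = as.numeric(table$sex))
  attr(X, "group") <- g
  X
}

#' Ordinary least squares fit of a GLM
#'
#' @param y Per-participant response vector.
#' @param design Design matrix from [make_design()] (or any full-rank
#'   numeric matrix).
#' @return List with `coefficients`, `residuals`, `fitted`.
#' @export
fit_glm <- function(y, design) {
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(design, y)
  list(coefficients = stats::setNames(fit$coefficients, colnames(design)),
       residuals = fit$residuals, fitted = fit$fitted.values)
}

#' Contrast vector between two groups
#'
#' Pairwise difference of fitted group means (first minus second), with
#' controls as the reference level of the design.
#'
#' @param group_a,group_b Group labels.
#' @param design A design matrix from [make_design()] (for column naming).
#' @return Named numeric contrast vector over the design columns.
#' @export
contrast_vector <- function(group_a, group_b, design) {
  cn <- colnames(design)
  v <- stats::setNames(numeric(length(cn)), cn)
  bump <- function(g, sgn) {
    if (g == "control") return()
    if (!g %in% cn) stop(sprintf("unknown group '%s'", g))
    v[g] <<- v[g] + sgn
  }
  bump(group_a, 1); bump(group_b, -1)
  v
}

new_contrast_estimate <- function(estimate, boot_se, ci95, bsr, p, n_boot,
                                  n_redraws = 0L) {
  structure(list(estimate = estimate, boot_se = boot_se, ci95 = ci95,
                 bsr = bsr, p_two_tailed = p, n_boot = n_boot,
                 n_redraws = n_redraws),
            class = "contrast_estimate")
}

#' @export
print.contrast_estimate <- function(x, ...) {
  cat(sprintf("<contrast_estimate> %.4f [%.4f, %.4f], SE %.4f, BSR %.2f, p = %.4g (%d boots)\n",
              x$estimate, x$ci95[1], x$ci95[2], x$boot_se, x$bsr,
              x$p_two_tailed, x$n_boot))
  invisible(x)
}

# Two-tailed percentile p-value of 0 under a bootstrap distribution,
# clipped to [1/n_boot, 1] so p is never exactly zero.
percentile_p <- function(boot) {
  n <- length(boot)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  min(max(p, 1 / n), 1)
}

# Participant-level resample indices that keep every group represented;
# degenerate draws are redrawn (counted, not skipped).
resample_indices <- function(group, n_boot) {
  n <- length(group)
  gi <- as.integer(group)
  ng <- length(unique(gi))
  idx <- matrix(0L, n, n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      ii <- sample.int(n, n, replace = TRUE)
      if (length(unique(gi[ii])) == ng) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot) stop("bootstrap cannot retain all groups")
    }
    idx[, b] <- ii
  }
  list(idx = idx, redraws = redraws)
}

#' Bootstrapped GLM group contrast
#'
#' Fits the GLM, then resamples participants with replacement (rows of the
#' response and design jointly), refitting the model on each of `n_boot`
#' draws. Reports the point estimate of the contrast, the bootstrap SE, the
#' 2.5/97.5 percentile CI, the bootstrap ratio BSR = estimate / SE (a
#' z-like statistic), and the two-tailed percentile p-value of 0 under the
#' bootstrap distribution. Draws that lose an entire group are redrawn so
#' the design stays full rank and `n_boot` is fixed.
#'
#' @param y Response vector.
#' @param design Design matrix from [make_design()].
#' @param contrast Contrast vector over design columns (see
#'   [contrast_vector()]).
#' @param n_boot Number of bootstrap draws (study convention: 2000).
#' @param seed Integer seed.
#' @param group Optional group factor (defaults to the design's `group`
#'   attribute) used to reject degenerate draws.
#' @return A `contrast_estimate`.
#' @export
bootstrap_contrast <- function(y, design, contrast, n_boot = 2000L, seed,
                               group = NULL) {
  if (is.null(group)) group <- attr(design, "group")
  if (is.null(group)) stop("supply 'group' or use a make_design() matrix")
  stopifnot(length(contrast) == ncol(design), length(y) == nrow(design))
  est <- sum(contrast * fit_glm(y, design)$coefficients)
  set.seed(as.integer(seed))
  rs <- resample_indices(group, n_boot)
  boot <- vapply(seq_len(n_boot), function(b) {
    ii <- rs$idx[, b]
    sum(contrast * stats::lm.fit(design[ii, , drop = FALSE], y[ii])$coefficients)
  }, numeric(1))
  if (rs$redraws > 0L)
    message(sprintf("bootstrap_contrast: %d degenerate draw(s) redrawn", rs$redraws))
  se <- stats::sd(boot)
  new_contrast_estimate(estimate = est, boot_se = se,
                        ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
                        bsr = est / se, p = percentile_p(boot),
                        n_boot = n_boot, n_redraws = rs$redraws)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up selection controlling the false discovery rate at level `q`.
#'
#' @param pvals Vector of p-values.
#' @param q FDR level (default 0.05).
#' @return Integer indices of the selected (significant) p-values.
#' @export
fdr_select <- function(pvals, q = 0.05) {
  which(stats::p.adjust(pvals, method = "BH") <= q)
}

#' Voxelwise bootstrapped group contrast
#'
#' Fits the GLM at every in-mask voxel and bootstraps the contrast with a
#' single participant-level resample sequence shared across voxels (one
#' draw resamples whole participants, preserving the spatial structure of
#' each map). Returns per-voxel estimate, BSR and two-tailed percentile
#' p-value maps.
#'
#' The voxelwise p-value defaults to a small-sample-calibrated tail of the
#' bootstrap ratio: the pairs bootstrap underestimates the OLS standard
#' error by a factor `sqrt((n - k) / n)` (its residual variance is
#' implicitly divided by `n`, not `n - k`), so the BSR is referred to a
#' `t` distribution with `n - k` degrees of freedom after rescaling by
#' that factor. This keeps the voxelwise false-positive rate at its
#' nominal level — the working assumption of Monte-Carlo cluster-size
#' thresholding — where the raw percentile p (available via
#' `p_method = "percentile"`) is tail-liberal at these group sizes.
#'
#' @param maps List of `hurst_map`s (or 3D arrays) — one metric map per
#'   participant — or a participants-by-voxels matrix.
#' @param mask 3D logical mask (required when `maps` are arrays).
#' @param design,contrast,n_boot,seed,group As in [bootstrap_contrast()].
#' @param p_method `"bsr_t"` (default, calibrated) or `"percentile"`.
#' @return List with 3D arrays `estimate`, `bsr`, `p` (NaN outside mask)
#'   and the shared `mask`; or plain vectors when `mask` is not given and
#'   `maps` is a matrix.
#' @export
voxelwise_contrast <- function(maps, design, contrast, n_boot = 2000L, seed,
                               mask = NULL, group = NULL,
                               p_method = c("bsr_t", "percentile")) {
  p_method <- match.arg(p_method)
  if (is.null(group)) group <- attr(design, "group")
  if (is.null(group)) stop("supply 'group' or use a make_design() matrix")
  as_array <- !is.matrix(maps) || !is.null(mask)
  if (!is.matrix(maps)) {
    if (inherits(maps[[1L]], "hurst_map")) {
      if (is.null(mask)) mask <- maps[[1L]]$mask
      maps <- lapply(maps, `[[`, "hurst")
    }
    if (is.null(mask)) stop("a mask is required for array input")
    Y <- do.call(rbind, lapply(maps, function(m) m[which(mask)]))
  } else Y <- maps
  stopifnot(nrow(Y) == nrow(design))
  bad <- !is.finite(Y)
  if (any(bad)) {        # rare failed voxel fits: impute participant mean
    for (i in which(rowSums(bad) > 0L))
      Y[i, bad[i, ]] <- mean(Y[i, !bad[i, ]])
  }
  cf <- qr.coef(qr(design), Y)
  est <- drop(contrast %*% cf)
  set.seed(as.integer(seed))
  rs <- resample_indices(group, n_boot)
  boot <- matrix(0, n_boot, ncol(Y))
  for (b in seq_len(n_boot)) {
    ii <- rs$idx[, b]
    boot[b, ] <- drop(contrast %*% qr.coef(qr(design[ii, , drop = FALSE]),
                                           Y[ii, , drop = FALSE]))
  }
  se <- apply(boot, 2L, stats::sd)
  bsr <- est / se
  if (p_method == "percentile") {
    ple <- colMeans(boot <= 0); pge <- colMeans(boot >= 0)
    p <- pmin(pmax(2 * pmin(ple, pge), 1 / n_boot), 1)
  } else {
    df <- nrow(design) - ncol(design)
    p <- 2 * stats::pt(-abs(bsr) * sqrt(df / nrow(design)), df = df)
  }
  if (!as_array)
    return(list(estimate = est, bsr = bsr, p = p, n_redraws = rs$redraws))
  blank <- array(NaN, dim(mask))
  E <- blank; E[which(mask)] <- est
  B <- blank; B[which(mask)] <- bsr
  P <- blank; P[which(mask)] <- p
  list(estimate = E, bsr = B, p = P, mask = mask, n_redraws = rs$redraws)
}
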