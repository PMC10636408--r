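sample_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / s^3
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^4) / s^4 - 3
}

#' Normality screen by skewness and kurtosis resampling
#'
#' Compares the sample skewness and excess kurtosis to a Monte-Carlo null
#' of `n_perm` same-size draws from a fitted Normal, with a two-tailed
#' percentile p-value per moment. The sample "deviates from normality" if
#' either p-value falls below `alpha`; this drives the choice between
#' mean (SD) and median [Q1, Q3] reporting for demographic variables.
#'
#' @param sample Numeric vector.
#' @param n_perm Number of null resamples (study convention: 5000).
#' @param alpha Per-moment significance level.
#' @param seed Integer seed.
#' @return List with `normal` (logical), `skew_p`, `kurt_p`, and the
#'   observed `skewness` and `kurtosis`.
#' @export
normality_screen <- function(sample, n_perm = 5000L, alpha = 0.05, seed) {
  x <- as.numeric(sample)
  n <- length(x)
  if (n < 8L) warning("very small sample: normality screen has little power")
  set.seed(as.integer(seed))
  null <- matrix(stats::rnorm(n * n_perm, mean(x), stats::sd(x)), n, n_perm)
  sk0 <- sample_skewness(x); ku0 <- sample_excess_kurtosis(x)
  skn <- apply(null, 2L, sample_skewness)
  kun <- apply(null, 2L, sample_excess_kurtosis)
  ptail <- function(obs, ref)
    min(max(2 * min(mean(ref <= obs), mean(ref >= obs)), 1 / length(ref)), 1)
  skew_p <- ptail(sk0, skn); kurt_p <- ptail(ku0, kun)
  list(normal = skew_p >= alpha && kurt_p >= alpha,
       skew_p = skew_p, kurt_p = kurt_p, skewness = sk0, kurtosis = ku0)
}

#' Prevalence with a percentile-bootstrap confidence interval
#'
#' @param k Number of symptom-positive participants.
#' @param n Group size.
#' @param n_boot Bootstrap draws (study convention: 2000).
#' @param seed Integer seed.
#' @return List with `percent`, `ci95` (both in percent) and `k`, `n`.
#' @export
prevalence_ci <- function(k, n, n_boot = 2000L, seed) {
  stopifnot(k >= 0, n >= 1, k <= n)
  x <- c(rep(1, k), rep(0, n - k))
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot),
                 function(b) 100 * mean(sample(x, n, replace = TRUE)),
                 numeric(1))
  list(percent = 100 * k / n,
       ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
       k = k, n = n)
}

#' Screening performance of a symptom for case status
#'
#' Treats symptom presence as a test for case (COVID) status:
#' sensitivity = symptom-positive cases / cases, specificity =
#' symptom-negative controls / controls, both in percent.
#'
#' @param pos_cases Symptom-positive participants among cases.
#' @param pos_controls Symptom-positive participants among controls.
#' @param n_cases,n_controls Group sizes.
#' @return List with `sensitivity` and `specificity` in percent.
#' @export
screening_performance <- function(pos_cases, pos_controls, n_cases,
                                  n_controls) {
  stopifnot(pos_cases <= n_cases, pos_controls <= n_controls)
  list(sensitivity = 100 * pos_cases / n_cases,
       specificity = 100 * (n_controls - pos_controls) / n_controls)
}

#' Bootstrapped two-sample mean difference
#'
#' Mean difference between two independent samples with bootstrap SE
#' (groups resampled independently), bootstrap ratio, percentile 95% CI
#' and two-tailed percentile p-value.
#'
#' @param x1,x2 Numeric samples; the difference is `mean(x1) - mean(x2)`.
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @return A `contrast_estimate`.
#' @export
two_sample_boot <- function(x1, x2, n_boot = 2000L, seed) {
  est <- mean(x1) - mean(x2)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b)
    mean(sample(x1, replace = TRUE)) - mean(sample(x2, replace = TRUE)),
    numeric(1))
  se <- stats::sd(boot)
  new_contrast_estimate(estimate = est, boot_se = se,
                        ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
                        bsr = est / se, p = percentile_p(boot),
                        n_boot = n_boot)
}

#' Spearman correlation with bootstrap CI and p-value
#'
#' Rank correlation (midranks for ties) with a percentile-bootstrap 95% CI
#' over resampled pairs and a two-tailed percentile p-value against 0.
#'
#' @param x,y Paired vectors (binary/ordinal x is fine).
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @return List with `rho`, `ci95`, `p_two_tailed`.
#' @export
spearman_ci <- function(x, y, n_boot = 2000L, seed) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    ii <- sample.int(n, n, replace = TRUE)
    r <- suppressWarnings(stats::cor(x[ii], y[ii], method = "spearman"))
    if (is.na(r)) 0 else r
  }, numeric(1))
  list(rho = rho, ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
       p_two_tailed = percentile_p(boot))
}

#' Symptom summary table for a case group
#'
#' For each non-reference symptom: ongoing prevalence with bootstrap CI,
#' difference in prevalence from the reference symptom (paired bootstrap
#' over participants) with CI and p-value, and — for symptoms with
#' prevalence of at least `rho_min_prev` — the Spearman correlation with
#' the reference symptom, with CI and p-value.
#'
#' @param symptoms data.frame of 0/1 ongoing-symptom indicators, one row
#'   per case participant, one column per symptom.
#' @param reference Column name of the reference symptom (default
#'   `"headache"`).
#' @param rho_min_prev Minimum prevalence (proportion) for reporting the
#'   correlation (default 0.10).
#' @param n_boot,seed Bootstrap settings.
#' @return data.frame with one row per non-reference symptom.
#' @export
symptom_summary <- function(symptoms, reference = "headache",
                            rho_min_prev = 0.10, n_boot = 2000L, seed) {
  stopifnot(reference %in% names(symptoms))
  ref <- symptoms[[reference]]
  n <- nrow(symptoms)
  others <- setdiff(names(symptoms), reference)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, 3L * length(others))
  rows <- lapply(seq_along(others), function(i) {
    sym <- symptoms[[others[i]]]
    prev <- prevalence_ci(sum(sym), n, n_boot, seeds[3 * i - 2])
    # paired difference in prevalence: resample participants jointly
    set.seed(seeds[3 * i - 1])
    dboot <- vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      100 * (mean(sym[ii]) - mean(ref[ii]))
    }, numeric(1))
    dp <- percentile_p(dboot)
    rho <- rho_lo <- rho_hi <- rho_p <- NA_real_
    if (mean(sym) >= rho_min_prev) {
      sp <- spearman_ci(sym, ref, n_boot, seeds[3 * i])
      rho <- sp$rho; rho_lo <- sp$ci95[1]; rho_hi <- sp$ci95[2]
      rho_p <- sp$p_two_tailed
    }
    data.frame(symptom = others[i], prevalence_pct = prev$percent,
               prev_lo = prev$ci95[1], prev_hi = prev$ci95[2],
               diff_from_ref_pct = 100 * (mean(sym) - mean(ref)),
               diff_lo = unname(stats::quantile(dboot, 0.025)),
               diff_hi = unname(stats::quantile(dboot, 0.975)),
               diff_p = dp, rho_with_ref = rho, rho_lo = rho_lo,
               rho_hi = rho_hi, rho_p = rho_p)
  })
  do.call(rbind, rows)
}
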