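default_config <- function() {
  list(
    seed = 1L,
    out_dir = "fractalbold-run",
    cohort = list(),                 # overrides for cohort_spec()
    estimator = "psd",
    estimator_params = list(),
    frequency_bounds = c(0.015, 0.225),
    inference = list(n_boot = 500L, p_voxel = 0.005, alpha = 0.05,
                     q_fdr = 0.05, n_sim = 500L,
                     contrasts = list(c("covid_h_plus", "covid_h_minus"),
                                      c("covid_h_r", "covid_h_minus"))),
    metrics = list(enabled = TRUE, half_width = 1L),
    symptoms = list(enabled = TRUE, n_boot = 2000L),
    figure_data = TRUE)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(user[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

validate_config <- function(cfg) {
  if (!cfg$estimator %in% c("psd", "dfa", "wma", "wlm"))
    stop(sprintf("unknown estimator '%s'", cfg$estimator))
  stopifnot(cfg$frequency_bounds[1] < cfg$frequency_bounds[2],
            cfg$inference$p_voxel > 0, cfg$inference$p_voxel < 1,
            cfg$inference$alpha > 0, cfg$inference$alpha < 1,
            cfg$inference$n_boot >= 100)
  for (ct in cfg$inference$contrasts)
    if (!all(ct %in% GROUP_LEVELS)) stop("unknown group in contrast: ",
                                         paste(ct, collapse = " vs "))
  invisible(cfg)
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[fractalbold] ", fmt), ...))

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 8) else col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full simulate - estimate - metrics - inference pipeline
#'
#' Sequences the package end to end on a synthetic cohort: cohort
#' simulation, voxelwise Hurst maps, global Hurst (gray-matter mean) GLM
#' contrasts with FDR control, voxelwise contrasts with smoothness-matched
#' Monte-Carlo cluster-size thresholding, cluster-ROI BOLD metric panels
#' with group contrasts, symptom summaries, per-group log-log spectrum
#' figure data, and a reproducibility manifest. All randomness flows from
#' the single config seed; rerunning with the same config is
#' reproducible, file for file.
#'
#' @param config A config list, or path to a YAML file with the same
#'   structure; see `fractalbold:::default_config()` for the full set of
#'   defaults (any subset may be supplied).
#' @return The manifest (invisibly), a list describing inputs, seed,
#'   config hash and every file written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  put <- function(df, name) {
    p <- write_tsv(df, file.path(out, name))
    outputs <<- c(outputs, name)
    p
  }

  stage_log("stage 1/6: simulating cohort (seed %d)", cfg$seed)
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  est_args <- cfg$estimator_params
  if (cfg$estimator == "psd" && length(est_args) == 0L)
    est_args <- list(f_min = cfg$frequency_bounds[1],
                     f_max = cfg$frequency_bounds[2])
  cohort <- simulate_cohort(spec, keep_volumes = cfg$metrics$enabled,
                            map_fun = function(v)
                              do.call(hurst_volume,
                                      c(list(v, estimator = cfg$estimator),
                                        est_args)))
  put(cohort$table, "cohort.tsv")

  stage_log("stage 2/6: voxelwise %s Hurst maps for %d participants",
            cfg$estimator, nrow(cohort$table))
  maps <- cohort$maps
  failed <- sum(vapply(maps, `[[`, 0L, "n_failed"))
  if (failed > 0L) stage_log("  %d voxel fits failed across cohort", failed)
  hglob <- vapply(maps, global_hurst, numeric(1))
  put(cbind(cohort$table[c("participant_id", "group")],
            data.frame(h_glob = hglob)), "hglob.tsv")

  stage_log("stage 3/6: global GLM bootstrap contrasts")
  design <- make_design(cohort$table)
  pairs <- utils::combn(GROUP_LEVELS[GROUP_LEVELS %in% cohort$table$group],
                        2L, simplify = FALSE)
  glob <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    ce <- bootstrap_contrast(hglob, design,
                             contrast_vector(pr[2], pr[1], design),
                             n_boot = cfg$inference$n_boot,
                             seed = cfg$seed + 100L + i)
    data.frame(contrast = paste(pr[2], "vs", pr[1]), estimate = ce$estimate,
               ci_lo = ce$ci95[1], ci_hi = ce$ci95[2], bsr = ce$bsr,
               p = ce$p_two_tailed)
  }))
  glob$fdr_significant <- seq_len(nrow(glob)) %in%
    fdr_select(glob$p, cfg$inference$q_fdr)
  put(glob, "contrasts_global.tsv")

  stage_log("stage 4/6: voxelwise contrasts + cluster-size thresholding")
  Y <- do.call(rbind, lapply(maps, function(m) m$hurst[which(cohort$mask)]))
  bad <- !is.finite(Y)
  if (any(bad))
    for (i in which(rowSums(bad) > 0L))
      Y[i, bad[i, ]] <- mean(Y[i, !bad[i, ]])
  cf <- qr.coef(qr(design), Y)
  resid_maps <- lapply(seq_len(nrow(Y)), function(i) {
    r <- array(NA_real_, spec$grid_shape)
    r[which(cohort$mask)] <- Y[i, ] - (design %*% cf)[i, ]
    r
  })
  fwhm <- estimate_smoothness(resid_maps, cohort$mask, spec$voxel_size)
  stage_log("  residual smoothness FWHM = %.2f/%.2f/%.2f mm",
            fwhm[1], fwhm[2], fwhm[3])
  all_centers <- NULL
  for (ci in seq_along(cfg$inference$contrasts)) {
    pr <- cfg$inference$contrasts[[ci]]
    tag <- paste(pr[1], "vs", pr[2], sep = "_")
    vw <- voxelwise_contrast(Y, design, contrast_vector(pr[1], pr[2], design),
                             n_boot = cfg$inference$n_boot,
                             seed = cfg$seed + 200L + ci, mask = cohort$mask)
    thr <- cluster_threshold(vw$p, cohort$mask,
                             p_voxel = cfg$inference$p_voxel,
                             alpha = cfg$inference$alpha, fwhm_mm = fwhm,
                             n_sim = cfg$inference$n_sim,
                             seed = cfg$seed + 300L + ci,
                             voxel_size = spec$voxel_size, bsr_map = vw$bsr)
    stage_log("  %s: min cluster size %d, %d cluster(s)", tag,
              thr$min_cluster_size, nrow(thr$clusters))
    put(thr$clusters, sprintf("clusters_%s.tsv", tag))
    write_nifti_vol(ifelse(is.finite(vw$bsr), vw$bsr, 0),
                    file.path(out, sprintf("bsr_%s.nii.gz", tag)),
                    spec$voxel_size)
    outputs <- c(outputs, sprintf("bsr_%s.nii.gz", tag))
    if (nrow(thr$clusters) > 0L) {
      ctr <- round(as.matrix(thr$clusters[, c("com_x", "com_y", "com_z")]) /
                     spec$voxel_size)
      all_centers <- rbind(all_centers, ctr)
    }
  }

  stage_log("stage 5/6: cluster-ROI BOLD metric panel")
  if (cfg$metrics$enabled && !is.null(all_centers)) {
    panel <- roi_panel(cohort$volumes, all_centers, cohort$mask,
                       half_width = cfg$metrics$half_width,
                       ids = cohort$table$participant_id)
    panel$group <- cohort$table$group
    put(panel, "metrics.tsv")
    mrows <- do.call(rbind, lapply(c("alff", "falff", "lconn", "gconn"),
      function(mn) {
        do.call(rbind, lapply(seq_along(cfg$inference$contrasts), function(ci) {
          pr <- cfg$inference$contrasts[[ci]]
          ce <- bootstrap_contrast(panel[[mn]], design,
                                   contrast_vector(pr[1], pr[2], design),
                                   n_boot = cfg$inference$n_boot,
                                   seed = cfg$seed + 400L + ci)
          data.frame(metric = mn, contrast = paste(pr[1], "vs", pr[2]),
                     estimate = ce$estimate, ci_lo = ce$ci95[1],
                     ci_hi = ce$ci95[2], bsr = ce$bsr, p = ce$p_two_tailed)
        }))
      }))
    put(mrows, "contrasts_metrics.tsv")
  } else stage_log("  skipped (no clusters or metrics disabled)")

  stage_log("stage 6/6: symptom summaries + figure data")
  if (cfg$symptoms$enabled) {
    covid <- cohort$table[cohort$table$group != "control", ]
    sym <- covid[, names(spec$symptom_prevalence[[1]])]
    sym$headache <- as.integer(covid$headache_status == "ongoing")
    put(symptom_summary(sym, "headache", n_boot = cfg$symptoms$n_boot,
                        seed = cfg$seed + 500L), "symptoms.tsv")
  }
  if (isTRUE(cfg$figure_data) && cfg$metrics$enabled) {
    # per participant: gray-matter mean banded PSD; per group: mean log power
    part_psd <- lapply(cohort$volumes, function(v) {
      est <- welch_psd_matrix(mask_matrix(v)$X, spec$tr)
      integrate_bands(spectral_density(est$freqs, rowMeans(est$power)))
    })
    f <- part_psd[[1]]$freqs
    fig <- do.call(rbind, lapply(split(seq_len(nrow(cohort$table)),
                                       cohort$table$group), function(ii) {
      ml <- unname(rowMeans(sapply(ii, function(i) log10(part_psd[[i]]$power))))
      sel <- f >= cfg$frequency_bounds[1] & f <= cfg$frequency_bounds[2]
      ft <- unname(stats::lm.fit(cbind(1, log10(f[sel])), ml[sel])$coefficients)
      data.frame(group = cohort$table$group[ii[1]], freq_hz = f,
                 log10_freq = log10(f), mean_log10_power = ml,
                 fitted = ft[1] + ft[2] * log10(f), beta = -ft[2])
    }))
    put(fig, "psd_figure.tsv")
  }

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(package = "fractalbold",
                   version = as.character(utils::packageVersion("fractalbold")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log("done: %d output files in %s", length(outputs) + 2L, out)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
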