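# Comparison BOLD measures at the detected clusters: 27-voxel cubic ROIs
# at each cluster center of mass give per-participant ALFF, fALFF, local
# and global connectivity (averaged over clusters); group contrasts are
# bootstrapped as for H, and the concordance of ROI-mean H with each
# metric is summarized with Spearman correlations.
source("analysis/00_common.R")

co <- study_cohort(keep_volumes = TRUE)
X <- make_design(co$table)
Y <- do.call(rbind, lapply(co$maps, function(m) m$hurst[which(co$mask)]))

vw <- voxelwise_contrast(Y, X,
                         contrast_vector("covid_h_plus", "covid_h_minus", X),
                         n_boot = 1000, seed = MASTER_SEED + 100,
                         mask = co$mask)
fwhm <- rep(co$spec$voxel_size, 3)
thr <- cluster_threshold(vw$p, co$mask, fwhm_mm = fwhm, n_sim = 2000,
                         seed = MASTER_SEED + 101,
                         voxel_size = co$spec$voxel_size, bsr_map = vw$bsr)
stopifnot(nrow(thr$clusters) > 0)
centers <- round(as.matrix(thr$clusters[, c("com_x", "com_y", "com_z")]) /
                   co$spec$voxel_size)

panel <- roi_panel(co$volumes, centers, co$mask,
                   ids = co$table$participant_id)
panel$group <- co$table$group
save_tsv(panel, "metric_panel.tsv")

mets <- c("alff", "falff", "lconn", "gconn")
contrasts <- do.call(rbind, lapply(seq_along(mets), function(i) {
  ce <- bootstrap_contrast(panel[[mets[i]]], X,
                           contrast_vector("covid_h_plus", "covid_h_minus", X),
                           n_boot = 2000, seed = MASTER_SEED + 110 + i)
  data.frame(metric = mets[i], estimate = signif(ce$estimate, 3),
             ci_lo = signif(ce$ci95[1], 3), ci_hi = signif(ce$ci95[2], 3),
             bsr = round(ce$bsr, 2), p = ce$p_two_tailed)
}))
save_tsv(contrasts, "metric_contrasts.tsv")

# concordance of per-participant ROI-mean H with each metric
roi_h <- vapply(seq_len(nrow(panel)), function(i) {
  vals <- vapply(seq_len(nrow(centers)), function(k) {
    r <- cubic_roi(centers[k, ], co$mask)
    mean(co$maps[[i]]$hurst[r$member_voxels], na.rm = TRUE)
  }, numeric(1))
  mean(vals)
}, numeric(1))
conc <- do.call(rbind, lapply(seq_along(mets), function(i) {
  sp <- spearman_ci(roi_h, panel[[mets[i]]], n_boot = 2000,
                    seed = MASTER_SEED + 120 + i)
  data.frame(metric = mets[i], rho = round(sp$rho, 2),
             ci_lo = round(sp$ci95[1], 2), ci_hi = round(sp$ci95[2], 2),
             p = sp$p_two_tailed)
}))
save_tsv(conc, "metric_concordance.tsv")
message(paste(capture.output(print(contrasts)), collapse = "\n"))
message(paste(capture.output(print(conc)), collapse = "\n"))
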