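#' Default ellipsoidal gray-matter mask
#'
#' An axis-aligned ellipsoid filling ~80% of each grid dimension — a stand-in
#' for a cortical gray-matter mask on a downsampled grid.
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @return 3D logical array.
#' @export
default_gm_mask <- function(grid_shape = c(16L, 16L, 16L)) {
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / (0.4 * d[a]))^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  r2 <= 1
}

#' Additive regional effect on the Hurst map
#'
#' @param region_mask 3D logical array marking the effect region.
#' @param delta_h Additive offset to the baseline Hurst exponent.
#' @return A `region_effect` object.
#' @export
region_effect <- function(region_mask, delta_h) {
  stopifnot(is.logical(region_mask) || all(region_mask %in% c(0, 1)))
  structure(list(region_mask = array(as.logical(region_mask),
                                     dim(region_mask)),
                 delta_h = delta_h),
            class = "region_effect")
}

# Default effect regions: compact blocks inside the mask. The "sensorimotor-
# like" superior block carries the ongoing-headache reduction; a separate
# lateral block carries the resolved-headache elevation.
default_effect_regions <- function(mask) {
  d <- dim(mask)
  ix <- slice.index(mask, 1L); iy <- slice.index(mask, 2L)
  iz <- slice.index(mask, 3L)
  superior <- mask & iz > 0.62 * d[3] & iy > 0.25 * d[2] & iy < 0.75 * d[2]
  lateral <- mask & iz <= 0.62 * d[3] & iz > 0.3 * d[3] & ix > 0.6 * d[1]
  list(covid_h_plus = superior, covid_h_r = lateral)
}

#' Specification of a synthetic multi-group cohort
#'
#' Defaults reproduce the study conditions: four groups of sizes
#' 17/32/14/11 (control, COVID without headache, with ongoing headache,
#' with resolved headache), 250-volume runs at TR 2.13 s, 3 mm voxels,
#' group age means/SDs and female fractions from the demographic table,
#' ongoing-symptom prevalences from the symptom table, and additive Hurst
#' offsets of -0.09 (ongoing headache) and +0.07 (resolved headache) in
#' compact effect regions, matching the scale of the observed global
#' contrasts. The spatial grid defaults to a 16^3 desk-scale stand-in for
#' the 3 mm MNI grid.
#'
#' @param group_sizes Named integer vector over the four group labels.
#' @param baseline_h Baseline Hurst exponent of every gray-matter voxel.
#' @param effects Named list (by group) of lists of [region_effect()]s;
#'   `NULL` uses the default regions, `list()` disables all effects.
#' @param age_mean,age_sd Named numeric vectors (years) per group.
#' @param female_fraction Named numeric vector per group.
#' @param symptom_prevalence Named list per group of named ongoing-symptom
#'   prevalences (proportions in [0, 1]).
#' @param control_resolved_headache Probability of resolved headache in the
#'   control group.
#' @param n_volumes,tr Run length (volumes) and repetition time (s).
#' @param grid_shape,voxel_size Spatial grid (voxels) and voxel size (mm).
#' @param mask Optional 3D logical mask (default [default_gm_mask()]).
#' @param sigma Marginal SD of each voxel series.
#' @param smooth_fwhm_mm Optional spatial smoothing of the simulated data.
#' @param seed Master seed; participant streams are derived as
#'   `seed + 7919 * participant_index` so any subset reproduces.
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(control = 17L, covid_h_minus = 32L,
                                        covid_h_plus = 14L, covid_h_r = 11L),
                        baseline_h = 0.7,
                        effects = NULL,
                        age_mean = c(control = 41.5, covid_h_minus = 40.3,
                                     covid_h_plus = 46.1, covid_h_r = 36.2),
                        age_sd = c(control = 13.1, covid_h_minus = 12.5,
                                   covid_h_plus = 10.1, covid_h_r = 10.6),
                        female_fraction = c(control = 0.59,
                                            covid_h_minus = 0.66,
                                            covid_h_plus = 0.79,
                                            covid_h_r = 0.55),
                        symptom_prevalence = NULL,
                        control_resolved_headache = 0.06,
                        n_volumes = 250L, tr = 2.13,
                        grid_shape = c(16L, 16L, 16L), voxel_size = 3,
                        mask = NULL, sigma = 1, smooth_fwhm_mm = 0,
                        seed = 1L) {
  group_sizes <- unlist(group_sizes)       # tolerate YAML-style lists
  if (!all(names(group_sizes) %in% GROUP_LEVELS))
    stop("group labels must be among: ", paste(GROUP_LEVELS, collapse = ", "))
  if (is.null(mask)) mask <- default_gm_mask(grid_shape)
  stopifnot(all(dim(mask) == grid_shape))
  if (is.null(effects)) {
    reg <- default_effect_regions(mask)
    effects <- list(
      covid_h_plus = list(region_effect(reg$covid_h_plus, -0.09)),
      covid_h_r = list(region_effect(reg$covid_h_r, +0.07)))
  }
  if (is.null(symptom_prevalence)) {
    ongoing <- c(fever = 0.00, cough = 0.14, sore_throat = 0.04,
                 shortness_of_breath = 0.25, fatigue = 0.32,
                 gastrointestinal = 0.09, smell_taste = 0.21)
    symptom_prevalence <- stats::setNames(
      rep(list(ongoing), length(group_sizes)), names(group_sizes))
  }
  for (g in names(symptom_prevalence))
    stopifnot(all(symptom_prevalence[[g]] >= 0),
              all(symptom_prevalence[[g]] <= 1))
  stopifnot(all(female_fraction >= 0 & female_fraction <= 1),
            baseline_h > 0.05, baseline_h < 0.95)
  structure(list(group_sizes = group_sizes, baseline_h = baseline_h,
                 effects = effects, age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 symptom_prevalence = symptom_prevalence,
                 control_resolved_headache = control_resolved_headache,
                 n_volumes = as.integer(n_volumes), tr = tr,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, mask = mask, sigma = sigma,
                 smooth_fwhm_mm = smooth_fwhm_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ground-truth Hurst map for one group
#'
#' Baseline plus the group's additive region effects, clipped to
#' (0.05, 0.95).
#'
#' @param spec A [cohort_spec()].
#' @param group Group label.
#' @return 3D array of H values (NA outside the mask).
#' @export
group_h_map <- function(spec, group) {
  h <- array(spec$baseline_h, spec$grid_shape)
  for (eff in spec$effects[[group]])
    h[eff$region_mask] <- h[eff$region_mask] + eff$delta_h
  h <- pmin(pmax(h, 0.05), 0.95)
  h[!spec$mask] <- NA_real_
  h
}

participant_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% .Machine$integer.max)
}

#' Simulate a full multi-group cohort
#'
#' Draws demographics, symptom tables and per-participant 4D fGn volumes
#' with the group's ground-truth Hurst map. Ages are Normal per group,
#' truncated to the eligibility window [20, 75]; sex is Bernoulli(female
#' fraction), coded 1 = female; ongoing symptoms are Bernoulli at the
#' specified prevalences; headache status is determined by group (none /
#' ongoing / resolved), with controls resolving headache at the specified
#' rate. Everything is a pure function of the spec (including its master
#' seed); per-participant volume streams are derived from the master seed
#' by a fixed counter scheme so that any subset of participants reproduces.
#'
#' @param spec A [cohort_spec()].
#' @param keep_volumes Keep the simulated 4D volumes (default `TRUE`).
#' @param map_fun Optional function applied to each participant's
#'   [volume_set()] as it is generated (e.g. `hurst_volume`); results are
#'   stored in `$maps` and the volume discarded unless `keep_volumes`.
#' @return A `cohort`: list with `table` (one row per participant),
#'   `volumes` (or `NULL`), `maps` (if `map_fun` given), `h_maps` (ground
#'   truth per group), `truth` (effect-region masks per group), `mask`, and
#'   the `spec`.
#' @export
simulate_cohort <- function(spec, keep_volumes = TRUE, map_fun = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  set.seed(spec$seed)
  age <- numeric(n); sex <- integer(n)
  onset_med <- c(control = 180, covid_h_minus = 151, covid_h_plus = 112,
                 covid_h_r = 126)
  test_med <- c(control = 141, covid_h_minus = 120, covid_h_plus = 112,
                covid_h_r = 124)
  days_onset <- numeric(n); days_test <- numeric(n)
  sym_names <- names(spec$symptom_prevalence[[groups[1L]]])
  sym <- matrix(0L, n, length(sym_names),
                dimnames = list(NULL, sym_names))
  headache <- character(n)
  for (i in seq_len(n)) {
    g <- groups[i]
    repeat {
      a <- stats::rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]])
      if (a >= 20 && a <= 75) break
    }
    age[i] <- a
    sex[i] <- stats::rbinom(1, 1, spec$female_fraction[[g]])
    days_onset[i] <- stats::rlnorm(1, log(onset_med[[g]]), 0.4)
    days_test[i] <- stats::rlnorm(1, log(test_med[[g]]), 0.4)
    sym[i, ] <- stats::rbinom(length(sym_names), 1,
                              spec$symptom_prevalence[[g]])
    headache[i] <- switch(g,
      control = if (stats::runif(1) < spec$control_resolved_headache)
        "resolved" else "none",
      covid_h_minus = "none",
      covid_h_plus = "ongoing",
      covid_h_r = "resolved")
  }
  table <- data.frame(participant_id = sprintf("sub-%03d", seq_len(n)),
                      group = groups, age = age, sex = sex,
                      headache_status = headache,
                      days_onset_to_scan = round(days_onset),
                      days_test_to_scan = round(days_test))
  table <- cbind(table, as.data.frame(sym))
  h_maps <- lapply(stats::setNames(nm = names(spec$group_sizes)),
                   function(g) group_h_map(spec, g))
  volumes <- if (keep_volumes) vector("list", n) else NULL
  maps <- if (!is.null(map_fun)) vector("list", n) else NULL
  for (i in seq_len(n)) {
    h <- h_maps[[groups[i]]]
    h[is.na(h)] <- spec$baseline_h    # out-of-mask values unused but valid
    vol <- simulate_volume(h, spec$mask, spec$n_volumes, spec$tr,
                           seed = participant_seed(spec$seed, i),
                           sigma = spec$sigma, voxel_size = spec$voxel_size,
                           smooth_fwhm_mm = spec$smooth_fwhm_mm)
    if (!is.null(map_fun)) maps[[i]] <- map_fun(vol)
    if (keep_volumes) volumes[[i]] <- vol
  }
  truth <- lapply(stats::setNames(nm = names(spec$effects)), function(g) {
    m <- array(FALSE, spec$grid_shape)
    for (eff in spec$effects[[g]]) m <- m | (eff$region_mask & spec$mask)
    m
  })
  structure(list(table = table, volumes = volumes, maps = maps,
                 h_maps = h_maps, truth = truth, mask = spec$mask,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%s), %s grid, %d volumes\n",
              nrow(x$table),
              paste(sprintf("%s=%d", names(table(x$table$group)),
                            table(x$table$group)), collapse = ", "),
              paste(x$spec$grid_shape, collapse = "x"), x$spec$n_volumes))
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + TSV table)
#'
#' Writes one 4D NIfTI per participant, the 3D mask, the per-group
#' ground-truth H maps, and the participant table as TSV.
#'
#' @param cohort A `cohort` with volumes retained.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$volumes)) stop("cohort has no stored volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$spec$voxel_size; tr <- cohort$spec$tr
  write_nifti_vol(cohort$mask * 1, file.path(dir, "mask.nii.gz"), vs)
  for (g in names(cohort$h_maps)) {
    h <- cohort$h_maps[[g]]; h[is.na(h)] <- 0
    write_nifti_vol(h, file.path(dir, sprintf("h_truth_%s.nii.gz", g)), vs)
  }
  for (i in seq_len(nrow(cohort$table)))
    write_nifti_vol(cohort$volumes[[i]]$data,
                    file.path(dir, sprintf("bold_%s.nii.gz",
                                           cohort$table$participant_id[i])),
                    vs, tr)
  utils::write.table(cohort$table, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
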