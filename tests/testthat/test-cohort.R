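small_spec <- function(...) {
  cohort_spec(grid_shape = c(8L, 8L, 8L), n_volumes = 64L, ...)
}

test_that("default cohort matches the study group sizes", {
  spec <- small_spec(seed = 31)
  co <- simulate_cohort(spec, keep_volumes = FALSE)
  expect_equal(unname(table(co$table$group)[c("control", "covid_h_minus",
                                              "covid_h_plus", "covid_h_r")]),
               c(17L, 32L, 14L, 11L),
               ignore_attr = TRUE)
  expect_equal(nrow(co$table), 74L)
})

test_that("cohort simulation is reproducible and subsets reproduce", {
  spec <- small_spec(seed = 32)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$volumes[[5]]$data, b$volumes[[5]]$data)
  # a participant's volume depends only on the master seed and its index
  spec_sub <- small_spec(seed = 32,
                         group_sizes = c(control = 2L, covid_h_minus = 2L,
                                         covid_h_plus = 2L, covid_h_r = 2L))
  sub <- simulate_cohort(spec_sub)
  expect_identical(sub$volumes[[2]]$data, a$volumes[[2]]$data)
})

test_that("demographics respect the eligibility window and coding", {
  spec <- small_spec(seed = 33)
  co <- simulate_cohort(spec, keep_volumes = FALSE)
  expect_true(all(co$table$age >= 20 & co$table$age <= 75))
  expect_true(all(co$table$sex %in% 0:1))
  expect_true(all(co$table$headache_status[co$table$group == "covid_h_plus"]
                  == "ongoing"))
  expect_true(all(co$table$headache_status[co$table$group == "covid_h_minus"]
                  == "none"))
  expect_true(all(co$table$headache_status[co$table$group == "covid_h_r"]
                  == "resolved"))
})

test_that("symptom prevalences track their specification", {
  spec <- cohort_spec(grid_shape = c(4L, 4L, 4L), n_volumes = 32L,
                      group_sizes = c(control = 100L, covid_h_minus = 100L,
                                      covid_h_plus = 100L, covid_h_r = 100L),
                      seed = 34)
  co <- simulate_cohort(spec, keep_volumes = FALSE)
  covid <- co$table[co$table$group != "control", ]
  expect_lt(abs(mean(covid$fatigue) - 0.32), 0.08)
  expect_equal(mean(covid$fever), 0)
  expect_lt(abs(mean(covid$shortness_of_breath) - 0.25), 0.08)
})

test_that("ground-truth maps add the group effects and clip", {
  spec <- small_spec(seed = 35)
  h_ctrl <- group_h_map(spec, "control")
  h_plus <- group_h_map(spec, "covid_h_plus")
  h_r <- group_h_map(spec, "covid_h_r")
  tr_plus <- spec$effects$covid_h_plus[[1]]$region_mask & spec$mask
  expect_equal(unique(h_plus[tr_plus] - h_ctrl[tr_plus]), -0.09)
  tr_r <- spec$effects$covid_h_r[[1]]$region_mask & spec$mask
  expect_equal(unique(h_r[tr_r] - h_ctrl[tr_r]), 0.07)
  expect_true(all(is.na(h_ctrl[!spec$mask])))
  clip <- cohort_spec(grid_shape = c(8L, 8L, 8L), baseline_h = 0.9,
                      seed = 1)
  expect_true(all(group_h_map(clip, "covid_h_r") <= 0.95, na.rm = TRUE))
})

test_that("a null cohort produces null group contrasts", {
  spec <- cohort_spec(grid_shape = c(6L, 6L, 6L), n_volumes = 250L,
                      effects = list(), seed = 36)
  co <- simulate_cohort(spec, keep_volumes = FALSE,
                        map_fun = function(v) hurst_volume(v, "psd"))
  hg <- vapply(co$maps, global_hurst, numeric(1))
  X <- make_design(co$table)
  ce <- bootstrap_contrast(hg, X,
                           contrast_vector("covid_h_plus", "covid_h_minus", X),
                           n_boot = 500, seed = 37)
  expect_true(ce$ci95[1] <= 0 && 0 <= ce$ci95[2])
})

test_that("cohorts round-trip through NIfTI + TSV", {
  spec <- cohort_spec(grid_shape = c(6L, 6L, 6L), n_volumes = 32L,
                      group_sizes = c(control = 2L, covid_h_minus = 2L,
                                      covid_h_plus = 2L, covid_h_r = 2L),
                      seed = 38)
  co <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "mask.nii.gz")))
  tab <- utils::read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(tab), 8L)
  v1 <- RNifti::readNifti(file.path(dir, "bold_sub-001.nii.gz"))
  expect_equal(dim(v1), c(6L, 6L, 6L, 32L))
  expect_equal(max(abs(as.numeric(v1) -
                         as.numeric(co$volumes[[1]]$data))), 0,
               tolerance = 1e-6)
})
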