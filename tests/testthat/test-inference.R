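test_that("design matrix encodes groups, centered age and sex", {
  tab <- demo_table()
  X <- make_design(tab)
  expect_equal(colnames(X), c("intercept", "covid_h_minus", "covid_h_plus",
                              "covid_h_r", "age", "sex"))
  expect_equal(sum(X[, "covid_h_plus"]), 14)
  expect_equal(mean(X[, "age"]), 0, tolerance = 1e-12)
  expect_true(all(rowSums(X[, 2:4]) <= 1))   # indicators mutually exclusive
  expect_error(make_design(data.frame(group = "patient", age = 1, sex = 0)),
               "unknown group")
})

test_that("fit_glm reproduces an exactly linear response", {
  tab <- demo_table()
  X <- make_design(tab)
  beta <- c(1, 0, -0.09, 0.07, 0.002, -0.01)
  y <- drop(X %*% beta)
  ft <- fit_glm(y, X)
  expect_equal(unname(ft$coefficients), beta, tolerance = 1e-10)
  expect_equal(max(abs(ft$residuals)), 0, tolerance = 1e-10)
  expect_error(fit_glm(y, cbind(X, X[, 2])), "rank-deficient")
})

test_that("bootstrap contrasts are deterministic given the seed", {
  tab <- demo_table()
  X <- make_design(tab)
  set.seed(2); y <- stats::rnorm(nrow(tab))
  cv <- contrast_vector("covid_h_plus", "control", X)
  a <- bootstrap_contrast(y, X, cv, n_boot = 200, seed = 9)
  b <- bootstrap_contrast(y, X, cv, n_boot = 200, seed = 9)
  expect_identical(a, b)
  expect_equal(a$bsr, a$estimate / a$boot_se)
  expect_true(a$ci95[1] <= a$ci95[2])
})

test_that("strong effects yield large bootstrap ratios", {
  tab <- demo_table()
  X <- make_design(tab)
  cv <- contrast_vector("covid_h_plus", "control", X)
  hits <- vapply(1:25, function(i) {
    set.seed(i); y <- stats::rnorm(nrow(tab), sd = 1)
    y[tab$group == "covid_h_plus"] <- y[tab$group == "covid_h_plus"] + 3
    ce <- bootstrap_contrast(y, X, cv, n_boot = 300, seed = 50 + i)
    abs(ce$bsr) > 2 && ce$p_two_tailed < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group offsets are recovered inside the bootstrap CI", {
  tab <- demo_table()
  X <- make_design(tab)
  truth <- c(covid_h_minus = 0, covid_h_plus = -0.09, covid_h_r = 0.07)
  cover <- vapply(1:30, function(i) {
    set.seed(1000 + i)
    y <- stats::rnorm(nrow(tab), sd = 0.1)
    for (g in names(truth)) y[tab$group == g] <- y[tab$group == g] + truth[g]
    ce <- bootstrap_contrast(y, X, contrast_vector("covid_h_plus", "control", X),
                             n_boot = 400, seed = 2000 + i)
    ce$ci95[1] <= -0.09 && -0.09 <= ce$ci95[2]
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("an age effect does not bias a contrast of age-matched groups", {
  sizes <- c(control = 40, covid_h_minus = 40, covid_h_plus = 40,
             covid_h_r = 40)
  ests <- vapply(1:40, function(i) {
    tab <- demo_table(sizes, seed = 3000 + i)
    X <- make_design(tab)
    set.seed(4000 + i)
    y <- 0.01 * tab$age + stats::rnorm(nrow(tab), sd = 0.05)
    sum(contrast_vector("covid_h_plus", "control", X) *
          fit_glm(y, X)$coefficients)
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.01)
})

test_that("BH step-up selection matches the hand-executed example", {
  expect_equal(fdr_select(c(0.001, 0.02, 0.04, 0.9)), c(1L, 2L))
  expect_length(fdr_select(rep(1, 10)), 0L)
  expect_equal(fdr_select(0.04), 1L)
})

test_that("degenerate bootstrap draws are redrawn, keeping n_boot", {
  tab <- demo_table(c(control = 3, covid_h_minus = 30, covid_h_plus = 30,
                      covid_h_r = 30))
  X <- make_design(tab)
  y <- stats::rnorm(nrow(tab))
  ce <- suppressMessages(
    bootstrap_contrast(y, X, contrast_vector("covid_h_minus", "control", X),
                       n_boot = 300, seed = 5))
  expect_equal(ce$n_boot, 300)
  expect_gt(ce$n_redraws, 0)
})

test_that("voxelwise contrast on one voxel equals the scalar bootstrap", {
  tab <- demo_table()
  X <- make_design(tab)
  set.seed(6); y <- stats::rnorm(nrow(tab))
  cv <- contrast_vector("covid_h_r", "covid_h_minus", X)
  sc <- bootstrap_contrast(y, X, cv, n_boot = 250, seed = 7)
  vx <- voxelwise_contrast(matrix(y, ncol = 1), X, cv, n_boot = 250, seed = 7,
                           p_method = "percentile")
  expect_equal(vx$estimate[1], sc$estimate, tolerance = 1e-12)
  expect_equal(vx$bsr[1], sc$bsr, tolerance = 1e-12)
  expect_equal(vx$p[1], sc$p_two_tailed, tolerance = 1e-12)
})

test_that("null voxelwise contrasts reject at close to the nominal rate", {
  tab <- demo_table()
  X <- make_design(tab)
  set.seed(8)
  Y <- matrix(stats::rnorm(nrow(tab) * 400), nrow(tab))
  vx <- voxelwise_contrast(Y, X, contrast_vector("covid_h_plus", "covid_h_minus", X),
                           n_boot = 400, seed = 9)
  expect_lt(mean(vx$p < 0.05), 0.10)
  expect_gt(mean(vx$p < 0.05), 0.01)
})

test_that("normality screen calibrates on Normal and flags exponential", {
  flags <- vapply(1:60, function(i) {
    set.seed(i)
    normality_screen(stats::rnorm(50), n_perm = 400, seed = 100 + i)$normal
  }, logical(1))
  expect_gte(mean(flags), 0.85)    # per-moment alpha=.05, two moments
  flags_exp <- vapply(1:40, function(i) {
    set.seed(i)
    normality_screen(stats::rexp(50), n_perm = 400, seed = 200 + i)$normal
  }, logical(1))
  expect_lte(mean(flags_exp), 0.10)
  expect_warning(normality_screen(c(1, 2, 3), n_perm = 50, seed = 1),
                 "small sample")
})

test_that("prevalence point estimates and CI edges behave", {
  pr <- prevalence_ci(14, 57, seed = 1)
  expect_equal(pr$percent, 100 * 14 / 57)
  expect_equal(round(pr$percent), 25)
  z <- prevalence_ci(0, 20, seed = 2)
  expect_equal(z$percent, 0); expect_equal(z$ci95[1], 0)
  f <- prevalence_ci(20, 20, seed = 3)
  expect_equal(f$percent, 100); expect_equal(f$ci95[2], 100)
})

test_that("screening performance reproduces hand-computed rates", {
  s <- screening_performance(14, 0, 57, 17)
  expect_equal(round(s$sensitivity), 25)
  expect_equal(s$specificity, 100)
  s2 <- screening_performance(25, 1, 57, 17)
  expect_equal(round(s2$sensitivity), 44)
  expect_equal(round(s2$specificity), 94)
  s3 <- screening_performance(10, 5, 10, 5)
  expect_equal(s3$sensitivity, 100); expect_equal(s3$specificity, 0)
})

test_that("spearman_ci: perfect association, null calibration, tuned rho", {
  x <- rep(0:1, each = 20)
  expect_equal(spearman_ci(x, x, n_boot = 200, seed = 1)$rho, 1)
  rej <- vapply(1:100, function(i) {
    set.seed(i)
    a <- stats::rbinom(60, 1, 0.4); b <- stats::rbinom(60, 1, 0.3)
    spearman_ci(a, b, n_boot = 200, seed = 300 + i)$p_two_tailed < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
  # contingency tuned to rho ~= 0.40 at prevalences 32% / 25% (n = 57):
  # counts (fatigue, headache): n11=9, n10=9, n01=5, n00=34
  fatigue <- rep(c(1, 1, 0, 0), c(9, 9, 5, 34))
  headache <- rep(c(1, 0, 1, 0), c(9, 9, 5, 34))
  sp <- spearman_ci(fatigue, headache, n_boot = 2000, seed = 11)
  expect_equal(sp$rho, 0.40, tolerance = 0.06)
  expect_true(sp$ci95[1] <= sp$rho && sp$rho <= sp$ci95[2])
  expect_lt(sp$p_two_tailed, 0.05)
})

test_that("symptom summary mirrors the reference-symptom comparisons", {
  set.seed(12)
  n <- 57
  sym <- data.frame(headache = stats::rbinom(n, 1, 0.25),
                    fatigue = stats::rbinom(n, 1, 0.32),
                    fever = rep(0, n))
  tab <- symptom_summary(sym, "headache", n_boot = 300, seed = 13)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$prevalence_pct[tab$symptom == "fever"], 0)
  expect_true(is.na(tab$rho_with_ref[tab$symptom == "fever"]))
  expect_false(is.na(tab$rho_with_ref[tab$symptom == "fatigue"]))
})
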