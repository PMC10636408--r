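# Demographic and symptom analytics on the synthetic cohort, mirroring the
# clinical workflow: normality screening decides mean(SD) vs median[Q1,Q3]
# reporting; group age/sex differences get bootstrapped contrasts; headache
# prevalence, its screening performance for case status, and the
# non-headache symptom comparison table are computed from the cohort table.
source("analysis/00_common.R")

co <- simulate_cohort(study_spec(), keep_volumes = FALSE)
tab <- co$table
groups <- unique(tab$group)

# -- normality screening per group and variable ------------------------------
screens <- do.call(rbind, lapply(c("age", "days_onset_to_scan"), function(v)
  do.call(rbind, lapply(groups, function(g) {
    x <- tab[[v]][tab$group == g]
    sc <- normality_screen(x, n_perm = 5000, seed = MASTER_SEED + 1)
    rep_txt <- if (sc$normal)
      sprintf("%.1f (%.1f)", mean(x), sd(x))
    else
      sprintf("%.0f [%.0f, %.0f]", median(x), quantile(x, .25),
              quantile(x, .75))
    data.frame(variable = v, group = g, normal = sc$normal,
               skew_p = sc$skew_p, kurt_p = sc$kurt_p, report = rep_txt)
  }))))
save_tsv(screens, "normality_screens.tsv")

# -- pairwise group differences in age --------------------------------------
pairs <- combn(groups, 2, simplify = FALSE)
age_diff <- do.call(rbind, lapply(seq_along(pairs), function(i) {
  pr <- pairs[[i]]
  ce <- two_sample_boot(tab$age[tab$group == pr[1]],
                        tab$age[tab$group == pr[2]],
                        n_boot = 2000, seed = MASTER_SEED + 10 + i)
  data.frame(contrast = paste(pr[1], "vs", pr[2]),
             mean_diff_years = round(ce$estimate, 1),
             ci_lo = round(ce$ci95[1], 1), ci_hi = round(ce$ci95[2], 1),
             bsr = round(ce$bsr, 2), p = ce$p_two_tailed)
}))
save_tsv(age_diff, "age_contrasts.tsv")

# -- headache prevalence and screening performance --------------------------
covid <- tab[tab$group != "control", ]
ctrl <- tab[tab$group == "control", ]
n_cov <- nrow(covid); n_ctl <- nrow(ctrl)
k_on <- sum(covid$headache_status == "ongoing")
k_re <- sum(covid$headache_status == "resolved")
pr_on <- prevalence_ci(k_on, n_cov, seed = MASTER_SEED + 30)
pr_re <- prevalence_ci(k_re, n_cov, seed = MASTER_SEED + 31)
sc_on <- screening_performance(k_on, sum(ctrl$headache_status == "ongoing"),
                               n_cov, n_ctl)
sc_cb <- screening_performance(k_on + k_re,
                               sum(ctrl$headache_status != "none"),
                               n_cov, n_ctl)
headache <- data.frame(
  quantity = c("prevalence_ongoing_pct", "prevalence_resolved_pct",
               "sensitivity_ongoing_pct", "specificity_ongoing_pct",
               "sensitivity_combined_pct", "specificity_combined_pct"),
  value = round(c(pr_on$percent, pr_re$percent, sc_on$sensitivity,
                  sc_on$specificity, sc_cb$sensitivity, sc_cb$specificity)),
  ci_lo = round(c(pr_on$ci95[1], pr_re$ci95[1], NA, NA, NA, NA)),
  ci_hi = round(c(pr_on$ci95[2], pr_re$ci95[2], NA, NA, NA, NA)))
save_tsv(headache, "headache_screening.tsv")

# -- other ongoing symptoms vs headache -------------------------------------
sym <- covid[, c("fever", "cough", "sore_throat", "shortness_of_breath",
                 "fatigue", "gastrointestinal", "smell_taste")]
sym$headache <- as.integer(covid$headache_status == "ongoing")
save_tsv(symptom_summary(sym, "headache", n_boot = 2000,
                         seed = MASTER_SEED + 40), "symptom_summary.tsv")

message(sprintf("ongoing headache: %d/%d (%.0f%%), screen sens/spec %.0f/%.0f%%",
                k_on, n_cov, pr_on$percent, sc_on$sensitivity,
                sc_on$specificity))
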