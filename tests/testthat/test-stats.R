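test_that("mode tabulation computes percentages and the 2:2 aggregate", {
  tm <- tabulate_modes(c("alternate" = 5005, "adjacent-1" = 3397,
                         "adjacent-2" = 1349, "3:1" = 585, "ND" = 510))
  expect_equal(tm$n_total, 10846)
  expect_equal(sum(tm$table$pct), 100)
  expect_equal(tm$two_two_n, 9751)
  expect_equal(round(tm$two_two_pct, 1), 89.9)
  one <- tabulate_modes(data.frame(mode = rep("adjacent-1", 7)))
  expect_equal(one$table$pct[one$table$mode == "adjacent-1"], 100)
  expect_error(tabulate_modes(data.frame(mode = character())), "empty")
})

test_that("simulated mode frequencies match the generating probabilities", {
  sim <- shared_sim()
  cohort <- shared_cohort()
  # truth-level: multinomial sampling error only
  tm <- tabulate_modes(data.frame(mode = sim$truth$true_mode))
  n <- tm$n_total
  expected <- c("alternate" = 46.1, "adjacent-1" = 31.3,
                "adjacent-2" = 12.4, "3:1" = 5.4) / 95.26 * 100
  for (m in names(expected)) {
    p <- expected[[m]] / 100
    se <- 100 * sqrt(p * (1 - p) / n)
    got <- tm$table$pct[tm$table$mode == m]
    # random-intercept variability shifts marginals slightly; allow 4 SE
    expect_lt(abs(got - expected[[m]]), max(4 * se, 2.5))
  }
})

test_that("odds ratios have symmetry, Haldane handling and sane errors", {
  o <- odds_ratio(c(10, 10, 10, 10))
  expect_equal(o$or_point, 1)
  expect_true(o$ci_low < 1 && o$ci_high > 1)
  # zero cell: Haldane-Anscombe correction keeps the estimate finite
  oz <- odds_ratio(c(5, 0, 3, 7))
  expect_true(is.finite(oz$or_point) && oz$or_point > 1)
  expect_error(odds_ratio(c(0, 0, 5, 5)), "margin")
  expect_error(odds_ratio(c(1, 2, 3)), "4 non-negative")
})

test_that("MH common OR matches the textbook formula to 1e-6", {
  strata <- list(c(1334, 816, 891, 851), c(2069, 1776, 1547, 1562))
  res <- cmh_analysis(strata)
  # independent oracle: Mantel-Haenszel weighted cross-product ratio
  mh_oracle <- {
    num <- sum(vapply(strata, function(t) t[1] * t[4] / sum(t), 0))
    den <- sum(vapply(strata, function(t) t[2] * t[3] / sum(t), 0))
    num / den
  }
  expect_equal(res$common_or, mh_oracle, tolerance = 1e-6)
  expect_lt(res$p_value, 1e-6)
})

test_that("identical strata are homogeneous; opposite strata are not", {
  same <- cmh_analysis(list(c(10, 10, 10, 10), c(10, 10, 10, 10)))
  expect_equal(same$common_or, 1)
  expect_gt(same$homogeneity_p, 0.9)
  # OR 2 vs OR 0.5 by construction, ~1000 per stratum
  opp <- cmh_analysis(list(c(400, 200, 250, 250), c(200, 400, 250, 250)))
  expect_lt(opp$homogeneity_p, 0.05)
})

test_that("homogeneity test agrees with an independent Woolf-test oracle", {
  strata <- list(c(1334, 816, 891, 851), c(2069, 1776, 1547, 1562))
  res <- cmh_analysis(strata)
  # Woolf heterogeneity chi-square as an independent approximation: the
  # two statistics are asymptotically equivalent, so their p-values should
  # agree to the leading order
  w <- vapply(strata, function(t) 1 / sum(1 / t), 0)
  lo <- vapply(strata, function(t) log(t[1] * t[4] / (t[2] * t[3])), 0)
  woolf_chi2 <- sum(w * (lo - weighted.mean(lo, w))^2)
  woolf_p <- pchisq(woolf_chi2, 1, lower.tail = FALSE)
  expect_lt(res$homogeneity_p, 0.001)      # the published conclusion
  expect_equal(log(res$homogeneity_p), log(woolf_p), tolerance = 0.1)
})

test_that("the common OR lies between same-direction stratum ORs", {
  res <- cmh_analysis(list(c(1334, 816, 891, 851),
                           c(2069, 1776, 1547, 1562)))
  expect_gte(res$common_or, min(res$stratum_or))
  expect_lte(res$common_or, max(res$stratum_or))
})

test_that("single stratum degenerates to the plain odds ratio", {
  expect_warning(res <- cmh_analysis(list(c(20, 10, 10, 20))), "single")
  expect_equal(res$common_or, odds_ratio(c(20, 10, 10, 20))$or_point)
})

test_that("with no clustering the GLMM agrees with ordinary logistic", {
  sim <- simulate_cohort(sim_config(n_carriers = 250, seed = 13,
                                    random_intercept_sd = 0))
  cohort <- build_cohort_table(sim)
  fit <- fit_binary_glmm(cohort, c("sex", "tar1"))
  ref <- glm(mode != "alternate" ~ sex + tar1, binomial(), cohort)
  for (term in c("sexfemale", "tar1")) {
    i <- match(term, fit$coefficients$term)
    expect_lt(abs(fit$coefficients$estimate[i] - coef(ref)[[term]]),
              2 * fit$coefficients$se[i])
  }
  expect_lt(fit$random_intercept_sd, 0.15)
  # nesting: fitted log-likelihood is no worse than the intercept-only fit
  null_fit <- suppressMessages(lme4::glmer(
    mode != "alternate" ~ 1 + (1 | carrier_id), cohort, binomial()))
  expect_gte(fit$log_lik, as.numeric(logLik(null_fit)))
})

test_that("degenerate covariates are reported by name", {
  cohort <- shared_cohort()
  cohort$constant <- 1
  expect_error(fit_binary_glmm(cohort, c("sex", "constant")), "constant")
  expect_error(fit_binary_glmm(cohort, "nope"), "nope")
})

test_that("univariate screening keeps strong effects and reports p-values", {
  cohort <- shared_cohort()
  sel <- select_covariates(cohort, c("sex", "acr_involved", "tar1", "age"))
  expect_true("sex" %in% sel)
  p <- attr(sel, "p_values")
  expect_equal(names(p), c("sex", "acr_involved", "tar1", "age"))
  expect_lt(p[["sex"]], 0.05)
  expect_gt(p[["age"]], 0.05)   # age has no generating effect
  # selection preserves candidate order
  expect_identical(as.character(sel),
                   intersect(c("sex", "acr_involved", "tar1", "age"), sel))
})

test_that("mode-specific contrasts recover mode-specific effects", {
  sim <- simulate_cohort(sim_config(n_carriers = 900, seed = 23,
                                    mode_effects = mode_specific_effects()))
  cohort <- build_cohort_table(sim)
  fits <- fit_multinomial_glmm(cohort, c("sex", "acr_involved", "tar1",
                                         "ts1"))
  expect_true(all(c("adjacent-1", "adjacent-2", "3:1") %in% names(fits)))
  # female effect on adjacent-2 (true OR 1.66) is detected and covered
  co <- fits[["adjacent-2"]]$coefficients
  i <- match("sexfemale", co$term)
  expect_true(co$ci_low[i] <= 1.66 && 1.66 <= co$ci_high[i])
  expect_gt(co$or[i], 1)
  # TAR1 strongly protective for adjacent-1 (true OR 0.316)
  co1 <- fits[["adjacent-1"]]$coefficients
  j <- match("tar1", co1$term)
  expect_true(co1$ci_low[j] <= 0.316 && 0.316 <= co1$ci_high[j])
})

test_that("all-alternate cohorts skip every contrast", {
  cohort <- shared_cohort()
  cohort$mode <- "alternate"
  w <- capture_warnings(fits <- fit_multinomial_glmm(cohort, "sex"))
  expect_length(w, 4)                      # one skip per contrast
  expect_match(w, "skipped", all = TRUE)
  expect_length(fits, 0)
})

test_that("AUC equals the pairwise exceedance probability", {
  cohort <- shared_cohort()[1:200, ]
  # need both classes in the subset
  expect_gt(length(unique(cohort$mode != "alternate")), 1)
  fit <- fit_binary_glmm(shared_cohort(), c("sex", "acr_involved", "tar1"))
  r <- roc_evaluate(fit, cohort)
  y <- cohort$mode != "alternate"
  score <- predict_risk(fit, cohort)
  # brute-force pairwise count with tie correction
  pairs <- outer(score[y], score[!y], `-`)
  auc_oracle <- mean((pairs > 0) + 0.5 * (pairs == 0))
  expect_equal(r$auc, auc_oracle, tolerance = 1e-12)
  expect_true(r$sensitivity >= 0 && r$sensitivity <= 1)
  expect_true(r$specificity >= 0 && r$specificity <= 1)
})

test_that("ROC errors on single-class labels", {
  cohort <- shared_cohort()
  fit <- fit_binary_glmm(cohort, "sex")
  one_class <- cohort[cohort$mode == "alternate", ]
  expect_error(roc_evaluate(fit, one_class), "single-class")
})
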