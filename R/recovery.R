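#' Coefficient-recovery experiment on synthetic cohorts
#'
#' End-to-end check of the pipeline: simulate cohorts with known generating
#' effects ([default_mode_effects()]: female OR 1.293, acrocentric
#' involvement OR 1.208, TAR1 OR 0.806 on the pooled unbalanced outcome,
#' random-intercept SD 0.5), classify every embryo from its CNV profile,
#' rebuild the cohort table, refit the binary random-intercept model, and
#' compare the recovered odds ratios with the generating truth.
#'
#' @param n_carriers carriers per replicate (default 2000).
#' @param n_reps replicates (default 20); each uses a seed derived from
#'   `seed`.
#' @param seed master seed.
#' @param covariates model covariates (default sex, acrocentric
#'   involvement, TAR1 — the generating ones).
#' @param use_truth_modes fit on the simulator's true modes instead of the
#'   classifier's calls (for isolating classification error; default FALSE).
#' @return list: `per_rep` (data.frame of per-replicate OR, CI and coverage
#'   per covariate), `summary` (per-covariate mean OR, true OR, CI coverage
#'   fraction), `truth` (named true ORs).
#' @export
recovery_experiment <- function(n_carriers = 2000, n_reps = 20, seed = 1,
                                covariates = c("sex", "acr_involved", "tar1"),
                                use_truth_modes = FALSE) {
  truth <- exp(default_mode_effects()[["adjacent-1"]])
  term_map <- c(sexfemale = "female", acr_involvedTRUE = "acr_involved",
                tar1 = "tar1", ts1 = "ts1_mb")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  per_rep <- list()
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_carriers = n_carriers, seed = rep_seeds[r])
    sim <- simulate_cohort(cfg)
    cohort <- build_cohort_table(sim)
    if (use_truth_modes) {
      cohort$mode <- sim$truth$true_mode[match(cohort$embryo_id,
                                               sim$truth$embryo_id)]
    }
    fit <- fit_binary_glmm(cohort, covariates)
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    co$covariate <- term_map[co$term]
    co$true_or <- unname(truth[co$covariate])
    co$covered <- co$ci_low <= co$true_or & co$true_or <= co$ci_high
    co$rep <- r
    co$n_obs <- fit$n_obs
    co$random_intercept_sd <- fit$random_intercept_sd
    per_rep[[r]] <- co
  }
  per_rep <- do.call(rbind, c(per_rep, make.row.names = FALSE))
  summary <- aggregate(cbind(or, covered) ~ covariate, per_rep, mean)
  names(summary) <- c("covariate", "mean_or", "coverage")
  summary$true_or <- unname(truth[summary$covariate])
  list(per_rep = per_rep, summary = summary,
       truth = truth[c("female", "acr_involved", "tar1")])
}
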