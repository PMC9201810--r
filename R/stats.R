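#' Tabulate segregation modes
#'
#' Counts and percentages per segregation mode over diagnosed embryos, plus
#' the 2:2 aggregate (alternate + adjacent-1 + adjacent-2).
#'
#' @param x either a cohort data.frame with a `mode` column, or a named
#'   vector of mode counts.
#' @return list with `table` (data.frame: mode, n, pct), `n_total`,
#'   `two_two_n` and `two_two_pct`.
#' @export
#' @examples
#' tabulate_modes(c(alternate = 5005, `adjacent-1` = 3397,
#'                  `adjacent-2` = 1349, `3:1` = 585, ND = 510))$table
tabulate_modes <- function(x) {
  counts <- if (is.data.frame(x)) {
    if (!nrow(x)) stop("empty cohort")
    tab <- table(factor(x$mode, levels = MODES_CALL))
    setNames(as.integer(tab), names(tab))
  } else {
    if (!length(x) || sum(x) == 0) stop("empty cohort")
    bad <- setdiff(names(x), MODES_CALL)
    if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
    x
  }
  counts <- counts[counts > 0 | names(counts) %in% MODES_CALL]
  n <- sum(counts)
  tab <- data.frame(mode = names(counts), n = as.integer(counts),
                    pct = 100 * as.numeric(counts) / n)
  two_two <- sum(tab$n[tab$mode %in% c("alternate", "adjacent-1", "adjacent-2")])
  list(table = tab, n_total = n, two_two_n = two_two,
       two_two_pct = 100 * two_two / n)
}

as_two_by_two <- function(t) {
  if (is.matrix(t)) t <- as.vector(t(t))
  if (length(t) != 4 || any(t < 0)) {
    stop("a 2x2 table needs 4 non-negative counts (a, b, c, d)")
  }
  setNames(as.numeric(t), c("a", "b", "c", "d"))
}

#' Odds ratio for a 2x2 table
#'
#' Point estimate (a*d)/(b*c) with the Haldane-Anscombe 0.5 continuity
#' correction when any cell is zero, Woolf log-normal 95\% CI, and a
#' chi-square p-value (no Yates correction, matching large-sample clinical
#' tables).
#'
#' @param t counts `(a, b, c, d)` = (exposed-event, exposed-nonevent,
#'   unexposed-event, unexposed-nonevent); a length-4 vector or 2x2 matrix
#'   in row-major order.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `or_result`: `or_point`, `ci_low`, `ci_high`,
#'   `p_value`, `table`.
#' @export
#' @examples
#' odds_ratio(c(1334, 816, 891, 851))$or_point   # 1.561
odds_ratio <- function(t, conf_level = 0.95) {
  t <- as_two_by_two(t)
  if (sum(t) == 0) stop("empty 2x2 table")
  if ((t["a"] == 0 && t["b"] == 0) || (t["c"] == 0 && t["d"] == 0) ||
      (t["a"] == 0 && t["c"] == 0) || (t["b"] == 0 && t["d"] == 0)) {
    stop("odds ratio undefined: an entire margin of the 2x2 table is zero")
  }
  tc <- if (any(t == 0)) t + 0.5 else t
  or <- (tc["a"] * tc["d"]) / (tc["b"] * tc["c"])
  se <- sqrt(sum(1 / tc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- suppressWarnings(
    chisq.test(matrix(t, 2, 2, byrow = TRUE), correct = FALSE)$p.value)
  structure(list(or_point = unname(or),
                 ci_low = unname(exp(log(or) - z * se)),
                 ci_high = unname(exp(log(or) + z * se)),
                 p_value = p, table = t), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or_point, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

breslow_day <- function(strata, common_or, tarone = FALSE) {
  # expected a-cell under the common OR solves a quadratic per stratum
  stat <- 0; resid_sum <- 0; var_sum <- 0
  for (t in strata) {
    n1 <- t["a"] + t["b"]; n2 <- t["c"] + t["d"]; m1 <- t["a"] + t["c"]
    R <- common_or
    # expected a-cell under the common OR with margins fixed solves
    # a*(n2 - m1 + a) = R*(n1 - a)*(m1 - a), i.e. the quadratic
    # (R-1)a^2 - [R(n1+m1) + n2 - m1]a + R*n1*m1 = 0; take the root
    # inside the admissible cell range
    A <- R - 1
    B <- -(R * (n1 + m1) + n2 - m1)
    C <- R * n1 * m1
    a_hat <- if (abs(A) < 1e-12) {
      -C / B
    } else {
      roots <- (-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A)
      roots[roots >= max(0, m1 - n2) & roots <= min(n1, m1)][1]
    }
    b_hat <- n1 - a_hat; c_hat <- m1 - a_hat; d_hat <- n2 - c_hat
    v <- 1 / (1 / a_hat + 1 / b_hat + 1 / c_hat + 1 / d_hat)
    stat <- stat + (t["a"] - a_hat)^2 / v
    resid_sum <- resid_sum + (t["a"] - a_hat)
    var_sum <- var_sum + v
  }
  if (tarone) stat <- stat - resid_sum^2 / var_sum
  df <- length(strata) - 1
  list(statistic = unname(stat), df = df,
       p_value = unname(pchisq(stat, df, lower.tail = FALSE)))
}

#' Cochran-Mantel-Haenszel analysis of stratified 2x2 tables
#'
#' Mantel-Haenszel common odds ratio and CMH chi-square test (continuity
#' correction off by default), with a Breslow-Day test of odds-ratio
#' homogeneity across strata (optionally with the Tarone adjustment). A
#' single stratum degenerates to the plain [odds_ratio()] with a warning.
#'
#' @param strata list of 2x2 tables, each as accepted by [odds_ratio()].
#' @param correct apply the continuity correction to the CMH statistic.
#' @param tarone apply the Tarone adjustment to the Breslow-Day statistic.
#' @return list of class `cmh_result`: `common_or`, `ci_low`, `ci_high`,
#'   `chi2`, `p_value`, `homogeneity_p`, `stratum_or` (per-stratum point
#'   estimates), `n_strata`.
#' @export
#' @examples
#' cmh_analysis(list(c(1334, 816, 891, 851),
#'                   c(2069, 1776, 1547, 1562)))$common_or
cmh_analysis <- function(strata, correct = FALSE, tarone = FALSE) {
  strata <- lapply(strata, as_two_by_two)
  if (any(vapply(strata, sum, 0) == 0)) stop("stratum with zero total")
  if (length(strata) < 2) {
    warning("single stratum: reporting the plain odds ratio", call. = FALSE)
    o <- odds_ratio(strata[[1]])
    return(structure(list(common_or = o$or_point, ci_low = o$ci_low,
                          ci_high = o$ci_high, chi2 = NA_real_,
                          p_value = o$p_value, homogeneity_p = NA_real_,
                          stratum_or = o$or_point, n_strata = 1L),
                     class = "cmh_result"))
  }
  arr <- array(unlist(lapply(strata, function(t)
    c(t["a"], t["c"], t["b"], t["d"]))),
    dim = c(2, 2, length(strata)))
  mh <- mantelhaen.test(arr, correct = correct, exact = FALSE)
  bd <- breslow_day(strata, unname(mh$estimate), tarone = tarone)
  structure(list(common_or = unname(mh$estimate),
                 ci_low = mh$conf.int[1], ci_high = mh$conf.int[2],
                 chi2 = unname(mh$statistic), p_value = mh$p.value,
                 homogeneity_p = bd$p_value,
                 stratum_or = vapply(strata, function(t)
                   odds_ratio(t)$or_point, 0),
                 n_strata = length(strata)), class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf(
    "MH common OR %.3f (95%% CI %.3f-%.3f), CMH chi2 %.2f, p = %.3g\nBreslow-Day homogeneity p = %.3g (%d strata)\n",
    x$common_or, x$ci_low, x$ci_high, x$chi2, x$p_value,
    x$homogeneity_p, x$n_strata))
  invisible(x)
}

check_covariates <- function(cohort, covariates) {
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    stop("covariate(s) not in cohort table: ", paste(missing, collapse = ", "))
  }
  for (cv in covariates) {
    if (length(unique(cohort[[cv]])) < 2) {
      stop("degenerate covariate '", cv, "': constant across all rows")
    }
  }
}

glmm_coef_table <- function(model, conf_level = 0.95) {
  sm <- summary(model)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"],
             or = exp(sm[, "Estimate"]),
             ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
             ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
             p_value = sm[, "Pr(>|z|)"], row.names = NULL)
}

#' Random-intercept logistic model for clustered embryo outcomes
#'
#' Fits unbalanced-vs-balanced (i.e. non-alternate vs alternate segregation,
#' ND counted as unbalanced) by a generalized linear mixed model with a
#' per-carrier random intercept, accounting for multiple embryos from the
#' same carrier. Fitting is maximum likelihood via the Laplace approximation
#' (lme4::glmer); odds ratios are exponentiated coefficients with Wald CIs.
#'
#' @param cohort cohort table (see [build_cohort_table()]); must contain
#'   `carrier_id`, `mode`, and the covariates. Segment sizes are in Mb.
#' @param covariates character vector of covariate column names.
#' @param outcome "unbalanced" (default) or the name of a logical column.
#' @param conf_level confidence level for the Wald CIs.
#' @return object of class `glmm_fit`: `coefficients` (term, estimate, se,
#'   or, ci_low, ci_high, p_value), `random_intercept_sd`, `converged`,
#'   `log_lik`, `n_obs`, `n_groups`, `outcome`, and the underlying `model`.
#' @export
fit_binary_glmm <- function(cohort, covariates, outcome = "unbalanced",
                            conf_level = 0.95) {
  if (length(unique(cohort$carrier_id)) < 2) {
    stop("need at least 2 carriers for a random-intercept fit")
  }
  check_covariates(cohort, covariates)
  y <- if (outcome == "unbalanced") cohort$mode != "alternate"
       else as.logical(cohort[[outcome]])
  if (length(unique(y)) < 2) stop("outcome is single-class")
  dat <- cohort[, c("carrier_id", covariates), drop = FALSE]
  dat$.y <- y
  # continuous covariates are standardized internally for optimizer
  # stability (sizes are in Mb, ratios in [0,1]); estimates and SEs are
  # transformed back to per-original-unit scale below
  scales <- setNames(rep(1, length(covariates)), covariates)
  centers <- setNames(rep(0, length(covariates)), covariates)
  for (cv in covariates) {
    if (is.numeric(dat[[cv]])) {
      scales[cv] <- stats::sd(dat[[cv]])
      centers[cv] <- mean(dat[[cv]])
      dat[[cv]] <- (dat[[cv]] - centers[cv]) / scales[cv]
    }
  }
  fml <- as.formula(paste(".y ~", paste(covariates, collapse = " + "),
                          "+ (1 | carrier_id)"))
  model <- suppressMessages(lme4::glmer(fml, data = dat, family = binomial()))
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  singular <- any(grepl("singular", msgs))
  msgs <- msgs[!grepl("singular", msgs)]   # boundary fits are valid optima
  conv <- length(msgs) == 0 && model@optinfo$conv$opt == 0
  if (!conv) {
    warning("GLMM did not converge cleanly: ",
            paste(msgs, collapse = "; "), call. = FALSE)
  }
  co <- glmm_coef_table(model, conf_level)
  for (cv in names(scales)[scales != 1]) {
    i <- co$term == cv
    co$estimate[i] <- co$estimate[i] / scales[cv]
    co$se[i] <- co$se[i] / scales[cv]
    co$or[i] <- exp(co$estimate[i])
    co$ci_low[i] <- exp(co$estimate[i] -
                          qnorm(1 - (1 - conf_level) / 2) * co$se[i])
    co$ci_high[i] <- exp(co$estimate[i] +
                           qnorm(1 - (1 - conf_level) / 2) * co$se[i])
  }
  vc <- lme4::VarCorr(model)
  structure(list(coefficients = co,
                 random_intercept_sd = attr(vc$carrier_id, "stddev")[[1]],
                 converged = conv, singular = singular,
                 log_lik = as.numeric(logLik(model)),
                 n_obs = nrow(dat),
                 n_groups = length(unique(dat$carrier_id)),
                 outcome = outcome, covariates = covariates,
                 centers = centers, scales = scales,
                 model = model), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "random-intercept logistic fit: %s, %d embryos / %d carriers\nrandom intercept SD %.3f, logLik %.1f%s\n",
    x$outcome, x$n_obs, x$n_groups, x$random_intercept_sd, x$log_lik,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Univariate screen of candidate covariates
#'
#' Fits one univariate random-intercept logistic model per candidate and
#' keeps those with p below `alpha` (Wald test on the covariate
#' coefficient), preserving the input order — the usual
#' univariate-to-multivariate selection step. Per-candidate fit errors are
#' downgraded to warnings so one degenerate candidate does not abort the
#' scan.
#'
#' @inheritParams fit_binary_glmm
#' @param candidates character vector of candidate covariate names.
#' @param alpha selection threshold (default 0.05).
#' @return character vector, subset of `candidates`; the per-candidate
#'   p-values are attached as attribute `p_values`.
#' @export
select_covariates <- function(cohort, candidates, alpha = 0.05,
                              outcome = "unbalanced") {
  pvals <- vapply(candidates, function(cv) {
    tryCatch({
      fit <- fit_binary_glmm(cohort, cv, outcome = outcome)
      # the non-intercept row(s); for a 2-level factor there is exactly one
      min(fit$coefficients$p_value[-1])
    }, error = function(e) {
      warning("candidate '", cv, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }, 0)
  keep <- candidates[!is.na(pvals) & pvals < alpha]
  attr(keep, "p_values") <- pvals
  keep
}

#' Per-mode contrasts versus alternate segregation
#'
#' The multinomial model is decomposed into independent binary
#' random-intercept contrasts, each non-alternate mode versus the alternate
#' reference — mirroring contrast-wise reporting of mode-specific odds
#' ratios. Contrasts with fewer than `min_events` events are skipped with a
#' warning.
#'
#' @inheritParams fit_binary_glmm
#' @param modes non-alternate modes to contrast (default adjacent-1,
#'   adjacent-2, 3:1, ND).
#' @param min_events minimum events per contrast.
#' @return named list of `glmm_fit` objects (skipped contrasts absent).
#' @export
fit_multinomial_glmm <- function(cohort, covariates,
                                 modes = c("adjacent-1", "adjacent-2",
                                           "3:1", "ND"),
                                 min_events = 10) {
  fits <- list()
  for (m in modes) {
    sub <- cohort[cohort$mode %in% c("alternate", m), , drop = FALSE]
    n_ev <- sum(sub$mode == m)
    if (n_ev < min_events) {
      warning("contrast ", m, " vs alternate skipped: only ", n_ev,
              " events", call. = FALSE)
      next
    }
    sub$.vs <- sub$mode == m
    fits[[m]] <- tryCatch(
      fit_binary_glmm(sub, covariates, outcome = ".vs"),
      error = function(e) {
        warning("contrast ", m, " vs alternate failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  Filter(Negate(is.null), fits)
}

#' Population-level risk score from a fitted model
#'
#' Predicted probability of the fit's outcome from the fixed effects only
#' (random intercepts set to zero: the score generalises to carriers not in
#' the fitting data).
#'
#' @param fit a `glmm_fit` from [fit_binary_glmm()].
#' @param cohort data with the fit's covariate columns.
#' @return numeric vector of probabilities.
#' @export
predict_risk <- function(fit, cohort) {
  stopifnot(inherits(fit, "glmm_fit"))
  dat <- cohort[, fit$covariates, drop = FALSE]
  for (cv in fit$covariates) {
    if (fit$scales[cv] != 1 || fit$centers[cv] != 0) {
      dat[[cv]] <- (dat[[cv]] - fit$centers[cv]) / fit$scales[cv]
    }
  }
  predict(fit$model, newdata = dat, type = "response", re.form = NA,
          allow.new.levels = TRUE)
}

#' ROC evaluation of a fitted segregation-risk model
#'
#' Scores each embryo by the model's fixed-effects predicted probability
#' (population-level: the random intercept of the embryo's own carrier is
#' not used, since the score is meant to be predictive for a new carrier)
#' and evaluates discrimination of the outcome. AUC is the rank statistic;
#' sensitivity and specificity are reported at the Youden-optimal threshold.
#'
#' @param fit a `glmm_fit` from [fit_binary_glmm()].
#' @param cohort the cohort table the fit was produced from (or comparable
#'   new data with the same columns).
#' @return list of class `roc_result`: `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `n_cases`, `n_controls`.
#' @export
roc_evaluate <- function(fit, cohort) {
  stopifnot(inherits(fit, "glmm_fit"))
  y <- if (fit$outcome == "unbalanced") cohort$mode != "alternate"
       else as.logical(cohort[[fit$outcome]])
  if (length(unique(y)) < 2) {
    stop("AUC undefined: outcome labels are single-class")
  }
  score <- predict_risk(fit, cohort)
  r <- pROC::roc(response = y, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]   # ties: first optimal threshold
  structure(list(auc = as.numeric(pROC::auc(r)),
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 threshold = best$threshold,
                 n_cases = sum(y), n_controls = sum(!y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f; at Youden threshold %.3f: sensitivity %.1f%%, specificity %.1f%%\n",
    x$auc, x$threshold, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
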