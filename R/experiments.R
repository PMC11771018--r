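# Simulation experiments validating the summary metrics: CI coverage,
# type-I error of the model-comparison test, and power against families of
# landmark-specific tests.

# fit the (unpenalized) landmark supermodel of a scenario to a raw draw
.fit_scenario <- function(raw, scn, covariates = c("Z1", "Z2", "Z3", "X"),
                          lambda = 0) {
  cohort <- .cohort_from_raw(raw, scn)
  grid <- landmark_grid(scn$landmarks, scn$window)
  stack <- build_stack(cohort, grid)
  penlm(stack, spec = td_spec(), penalty = penalty_spec(lambda = lambda),
        causes = 1L, covariates = covariates)
}

# evaluate both metric curves of a fit on a raw test draw
.eval_curves <- function(fit, raw_test, scn) {
  nd <- .pred_frame_raw(raw_test, scn)
  risks <- suppressWarnings(stats::predict(fit, nd))
  outcomes <- data.frame(id = seq_along(raw_test$time), time = raw_test$time,
                         status = raw_test$status)
  list(auc = metric_curve(risks, outcomes, window = scn$window,
                          landmarks = scn$landmarks, metric = "auc",
                          risk_col = "risk_cause1"),
       bs = metric_curve(risks, outcomes, window = scn$window,
                         landmarks = scn$landmarks, metric = "bs",
                         risk_col = "risk_cause1"))
}

#' Coverage experiment for the summary-metric confidence intervals
#'
#' For each scenario: repeatedly simulates independent training and test
#' cohorts, fits the landmark supermodel on the training data, forms the
#' influence-function CI of the summary AUC and Brier score on the test
#' data, and scores whether each CI contains the fitted model's population
#' value (a Monte-Carlo oracle computed on a large uncensored cohort).
#'
#' @param scenarios a [sim_scenario()] or list of them.
#' @param reps replicates per scenario.
#' @param level nominal confidence level.
#' @param seed integer seed; replicates are seeded reproducibly per
#'   scenario.
#' @param n_mc size of the Monte-Carlo oracle cohort.
#' @return list with `table` (one row per scenario and metric: coverage,
#'   binomial MC standard error, replicates used, failures) and `mean`
#'   (mean coverage per metric across scenarios, in percent).
#' @export
run_coverage_experiment <- function(scenarios, reps = 500L, level = 0.95,
                                    seed = 1L, n_mc = 100000L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    cache <- .truth_cache(scn, n_mc, seed = seed + 611953L * si)
    hit <- matrix(NA, reps, 2L, dimnames = list(NULL, c("auc", "bs")))
    fails <- 0L
    for (r in seq_len(reps)) {
      res <- tryCatch({
        .with_seed(seed + 7919L * si + r, {
          raw_tr <- .sim_raw(scn)
          raw_te <- .sim_raw(scn)
          fit <- .fit_scenario(raw_tr, scn)
          cv <- .eval_curves(fit, raw_te, scn)
          truth <- .true_summary_cached(cache, fit)
          sa <- summary_metric(cv$auc, level = level)
          sb <- summary_metric(cv$bs, level = level)
          c(auc = truth["auc"] >= sa$lower && truth["auc"] <= sa$upper,
            bs = truth["bs"] >= sb$lower && truth["bs"] <= sb$upper)
        })
      }, error = function(e) NULL)
      if (is.null(res)) fails <- fails + 1L else hit[r, ] <- res
    }
    used <- colSums(!is.na(hit))
    cov <- colMeans(hit, na.rm = TRUE)
    rows[[si]] <- data.frame(
      n = scn$n, k = scn$k, lmi = scn$lmi, censor_rate = scn$censor_rate,
      metric = c("auc", "bs"), coverage = as.numeric(cov),
      mc_se = sqrt(cov * (1 - cov) / pmax(used, 1L)),
      reps_used = as.integer(used), failures = fails)
  }
  table <- do.call(rbind, rows)
  mean_cov <- 100 * c(auc = mean(table$coverage[table$metric == "auc"]),
                      bs = mean(table$coverage[table$metric == "bs"]))
  list(table = table, mean = mean_cov)
}

#' Type-I-error experiment for the model-comparison test
#'
#' Fits two "equivalent" models -- supermodels of identical structure whose
#' population performance is exactly equal by construction -- to one
#' training cohort, evaluates both on an independent test cohort, and
#' collects the two-sided p-values of the summary-metric difference test.
#' Equivalence exploits the generator's symmetric design: Z1 (effect
#' `beta[1]`) and Z2 (effect `beta[2] = -beta[1]`) are exchangeable up to
#' sign, so the model using (Z1, Z3, X) and the model using (Z2, Z3, X)
#' have identical population AUC and Brier curves, giving an exact null.
#' Under it the rejection rate should match the nominal level.
#'
#' @param scenario a [sim_scenario()] (the reference design uses n = 3000);
#'   `beta[1]` and `beta[2]` must have equal magnitude.
#' @param reps number of replicates.
#' @param levels significance levels at which to report rejection rates.
#' @param seed integer seed.
#' @return data frame: metric, level, rejection rate, binomial MC standard
#'   error, replicates used.
#' @export
run_type1_experiment <- function(scenario, reps = 500L,
                                 levels = c(0.01, 0.05, 0.10), seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (abs(abs(scenario$beta[1L]) - abs(scenario$beta[2L])) > 1e-12)
    warning("beta[1] and beta[2] differ in magnitude: the two models are ",
            "not exactly equivalent and rejection rates exceed the level")
  pv <- matrix(NA_real_, reps, 2L, dimnames = list(NULL, c("auc", "bs")))
  fails <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      .with_seed(seed + 104729L + r, {
        raw_tr <- .sim_raw(scenario)
        raw_te <- .sim_raw(scenario)
        f1 <- .fit_scenario(raw_tr, scenario, covariates = c("Z1", "Z3", "X"))
        f2 <- .fit_scenario(raw_tr, scenario, covariates = c("Z2", "Z3", "X"))
        c1 <- .eval_curves(f1, raw_te, scenario)
        c2 <- .eval_curves(f2, raw_te, scenario)
        c(auc = compare_models(c1$auc, c2$auc)$p_value,
          bs = compare_models(c1$bs, c2$bs)$p_value)
      })
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else pv[r, ] <- res
  }
  used <- colSums(!is.na(pv))
  out <- expand.grid(metric = c("auc", "bs"), level = levels,
                     stringsAsFactors = FALSE)
  out$rejection_rate <- mapply(function(mt, lv) mean(pv[, mt] < lv, na.rm = TRUE),
                               out$metric, out$level)
  out$mc_se <- sqrt(out$rejection_rate * (1 - out$rejection_rate) /
                      pmax(used[out$metric], 1L))
  out$reps_used <- as.integer(used[out$metric])
  out$failures <- fails
  out
}

#' Power experiment: summary test vs adjusted landmark-specific tests
#'
#' Compares a full supermodel M1 (fixed covariates plus the longitudinal
#' covariate) against a reduced model M2 omitting the longitudinal
#' covariate, both fitted to the same training cohort and evaluated on one
#' test cohort.  Per replicate it records (i) the p-value of the summary
#' difference test and (ii) the family of k landmark-specific difference
#' tests adjusted by Bonferroni and Benjamini-Hochberg (the family rejects
#' when any adjusted p-value is below the level).  Returns the empirical
#' power of the three procedures per scenario and metric.
#'
#' @param scenarios a [sim_scenario()] or list of them (e.g. a grid over
#'   sample size n and number of landmarks k).
#' @param reps replicates per scenario.
#' @param level significance level.
#' @param seed integer seed.
#' @return data frame: n, k, censor_rate, metric, procedure
#'   (summary / bonferroni / bh), power, MC standard error.
#' @export
run_power_experiment <- function(scenarios, reps = 500L, level = 0.05,
                                 seed = 1L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    rej <- array(NA, c(reps, 2L, 3L),
                 dimnames = list(NULL, c("auc", "bs"),
                                 c("summary", "bonferroni", "bh")))
    fails <- 0L
    for (r in seq_len(reps)) {
      res <- tryCatch({
        .with_seed(seed + 15485863L * si + r, {
          raw_tr <- .sim_raw(scn)
          raw_te <- .sim_raw(scn)
          f1 <- .fit_scenario(raw_tr, scn)
          f2 <- .fit_scenario(raw_tr, scn, covariates = c("Z1", "Z2", "Z3"))
          c1 <- .eval_curves(f1, raw_te, scn)
          c2 <- .eval_curves(f2, raw_te, scn)
          out <- matrix(NA, 2L, 3L)
          for (mi in 1:2) {
            cmp <- compare_models(c1[[mi]], c2[[mi]])
            out[mi, 1L] <- cmp$p_value < level
            out[mi, 2L] <- isTRUE(attr(adjust_pvalues(cmp$landmarks$p_value,
                                                      "bonferroni", level),
                                       "reject_family"))
            out[mi, 3L] <- isTRUE(attr(adjust_pvalues(cmp$landmarks$p_value,
                                                      "BH", level),
                                       "reject_family"))
          }
          out
        })
      }, error = function(e) NULL)
      if (is.null(res)) fails <- fails + 1L else rej[r, , ] <- res
    }
    used <- sum(!is.na(rej[, 1L, 1L]))
    pw <- apply(rej, c(2L, 3L), mean, na.rm = TRUE)
    rows[[si]] <- data.frame(
      n = scn$n, k = scn$k, censor_rate = scn$censor_rate,
      metric = rep(rownames(pw), 3L),
      procedure = rep(colnames(pw), each = 2L),
      power = as.numeric(pw),
      mc_se = sqrt(as.numeric(pw) * (1 - as.numeric(pw)) / max(used, 1L)),
      reps_used = used, failures = fails)
  }
  do.call(rbind, rows)
}
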