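#' Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator of the censoring survival G, treating events of
#' any cause as censoring of the censoring process.  Used to build inverse
#' probability of censoring weights; valid under independent censoring.
#'
#' @param outcomes data frame with columns `time` and `status`
#'   (0 = censored), or an `lm_cohort`.
#' @return An object of class `lm_censkm`: a step function representation
#'   with `time` (censoring jump times), `surv`, and evaluators accessible
#'   via [km_at()].
#' @export
censoring_km <- function(outcomes) {
  if (inherits(outcomes, "lm_cohort")) outcomes <- outcomes$outcomes
  if (nrow(outcomes) == 0L) stop("outcomes are empty")
  sf <- survival::survfit(survival::Surv(outcomes$time, outcomes$status == 0) ~ 1)
  keep <- sf$n.event > 0
  structure(list(time = sf$time[keep], surv = sf$surv[keep], n = sf$n),
            class = "lm_censkm")
}

#' Evaluate a censoring Kaplan-Meier curve
#'
#' @param km an `lm_censkm`.
#' @param t evaluation times.
#' @param left if `TRUE`, evaluate the left limit G(t-).
#' @return Numeric vector of survival probabilities.
#' @export
km_at <- function(km, t, left = FALSE) {
  idx <- findInterval(t, km$time, left.open = left)
  c(1, km$surv)[idx + 1L]
}

# shared set-up for the time-dependent metrics at one landmark
.metric_frame <- function(risk, outcomes, s, window) {
  if (inherits(outcomes, "lm_cohort")) outcomes <- outcomes$outcomes
  n <- nrow(outcomes)
  if (length(risk) != n)
    stop("risk must align with the outcome rows (length ", n, ")")
  ss <- which(outcomes$time > s)
  if (!length(ss)) stop("no subjects at risk at landmark s = ", s)
  r <- risk[ss]
  if (anyNA(r))
    stop("missing predicted risks for subjects at risk at s = ", s)
  list(n = n, ss = ss, time = outcomes$time[ss], status = outcomes$status[ss],
       risk = r, tau = s + window)
}

# IPCW weights at a landmark: conditional censoring KM Ghat(.|s) computed on
# the at-risk subsample (equivalent to the marginal KM ratio Ghat(.)/Ghat(s))
.ipcw_weights <- function(fr, include_competing = TRUE) {
  is_cens <- fr$status == 0
  km <- .cens_km_eval(fr$time, is_cens)
  case <- fr$time <= fr$tau & fr$status == 1
  surv <- fr$time > fr$tau
  comp <- if (include_competing) fr$time <= fr$tau & fr$status >= 2 else
    rep(FALSE, length(fr$time))
  Gm <- km$at_left(fr$time)
  Gtau <- km$at(fr$tau)
  if (any(case & Gm <= 0) || any(comp & Gm <= 0))
    stop("censoring survival is 0 at an event time needed for weighting")
  if (any(surv) && Gtau <= 0)
    stop("censoring survival is 0 at the horizon t = ", fr$tau,
         "; weights undefined")
  W_case <- ifelse(case, 1 / Gm, 0)
  W_ctrl <- ifelse(surv, 1 / Gtau, 0) + ifelse(comp, 1 / Gm, 0)
  list(case = case, surv = surv, comp = comp, W_case = W_case,
       W_ctrl = W_ctrl, is_cens = is_cens, Gtau = Gtau)
}

#' Time-dependent AUC with IPCW
#'
#' Estimates AUC(s, s+w): the probability that a subject experiencing the
#' event of interest (cause 1) during (s, s+w] received a higher predicted
#' risk than a subject who did not, among subjects still at risk at s.
#' Controls are subjects event-free at s+w together with competing-cause
#' events in the window (configurable).  Censoring is handled by inverse
#' probability of censoring weights from the conditional Kaplan-Meier
#' estimator; ties in predicted risk count one half.  Alongside the
#' estimate, the estimator's first-order influence values (including the
#' censoring-estimation term) are returned for every subject of the full
#' test sample, with zeros for subjects not at risk at s.
#'
#' @param risk predicted w-year risks, aligned with the rows of `outcomes`
#'   (may be NA for subjects not at risk at s).
#' @param outcomes full test-sample outcomes (`time`, `status`) or an
#'   `lm_cohort`.
#' @param s landmark time.
#' @param window prediction window w.
#' @param include_competing treat competing-cause events in the window as
#'   controls (default) or exclude them.
#' @return list with `estimate`, `influence` (length n, mean zero), `n`,
#'   `n_at_risk`, `n_case`, `n_control`.
#' @export
td_auc <- function(risk, outcomes, s, window, include_competing = TRUE) {
  fr <- .metric_frame(risk, outcomes, s, window)
  wt <- .ipcw_weights(fr, include_competing)
  ns <- length(fr$ss)
  W1 <- wt$W_case; W2 <- wt$W_ctrl
  n_case <- sum(wt$case); n_ctrl <- sum(wt$surv | wt$comp)
  if (n_case == 0L || n_ctrl == 0L)
    stop("AUC undefined at s = ", s, ": ", n_case, " cases and ",
         n_ctrl, " controls")

  # weighted Mann-Whitney sums via a single sort, ties counted one half
  o <- order(fr$risk)
  grp <- cumsum(!duplicated(fr$risk[o]))
  gsum <- function(wv) {
    gs <- rowsum(wv[o], grp)[, 1L]
    gs
  }
  s1 <- gsum(W1); s2 <- gsum(W2)
  below2 <- cumsum(s2) - s2            # control weight strictly below group
  above1 <- sum(s1) - cumsum(s1)       # case weight strictly above group
  gi <- grp[order(o)]                  # group of each subject
  A <- below2[gi] + 0.5 * s2[gi]       # per-case control mass beaten (+ half ties)
  B <- above1[gi] + 0.5 * s1[gi]       # per-control case mass above (+ half ties)

  Fhat <- mean(W1); Shat <- mean(W2)
  N <- sum(W1 * A) / ns^2
  auc <- N / (Fhat * Shat)

  proj <- (W1 * A + W2 * B) / ns - 2 * N
  lsum <- .cens_if_builder(fr$time, wt$is_cens)
  u_evt <- fr$time
  # G-term of the numerator: each weighted summand contributes at the point
  # where its weight evaluates Ghat (event left limits; tau for survivors)
  u <- c(u_evt, rep(fr$tau, ns))
  open <- c(rep(TRUE, ns), rep(FALSE, ns))
  ccN <- c((W1 * A + ifelse(wt$comp, W2 * B, 0)) / ns^2,
           ifelse(wt$surv, W2 * B, 0) / ns^2)
  GN <- lsum(u, ccN, open)
  GF <- lsum(u_evt, W1 / ns, rep(TRUE, ns))
  GS <- lsum(u, c(ifelse(wt$comp, W2, 0) / ns, ifelse(wt$surv, W2, 0) / ns), open)

  phi_cond <- (proj + GN) / (Fhat * Shat) -
    auc * ((W1 - Fhat + GF) / Fhat + (W2 - Shat + GS) / Shat)
  phi <- numeric(fr$n)
  phi[fr$ss] <- (fr$n / ns) * phi_cond
  list(estimate = auc, influence = phi, n = fr$n, n_at_risk = ns,
       n_case = n_case, n_control = n_ctrl)
}

#' Time-dependent Brier score with IPCW
#'
#' Estimates BS(s, s+w): the mean squared difference between the cause-1
#' event indicator over (s, s+w] and the predicted risk, among subjects at
#' risk at s, with inverse probability of censoring weights.  Returns the
#' estimate and full-sample influence values as in [td_auc()].
#'
#' @inheritParams td_auc
#' @return list with `estimate`, `influence`, `n`, `n_at_risk`.
#' @export
td_brier <- function(risk, outcomes, s, window, include_competing = TRUE) {
  fr <- .metric_frame(risk, outcomes, s, window)
  ns <- length(fr$ss)
  is_cens <- fr$status == 0
  km <- .cens_km_eval(fr$time, is_cens)
  known_event <- fr$time <= fr$tau & fr$status >= 1
  surv <- fr$time > fr$tau
  D <- as.numeric(fr$time <= fr$tau & fr$status == 1)
  Gm <- km$at_left(fr$time)
  Gtau <- km$at(fr$tau)
  if (any(known_event & Gm <= 0))
    stop("censoring survival is 0 at an event time needed for weighting")
  if (any(surv) && Gtau <= 0)
    stop("censoring survival is 0 at the horizon t = ", fr$tau,
         "; weights undefined")
  W <- ifelse(known_event, 1 / Gm, 0) + ifelse(surv, 1 / Gtau, 0)
  sq <- (D - fr$risk)^2
  bs <- mean(W * sq)

  lsum <- .cens_if_builder(fr$time, is_cens)
  u <- c(fr$time, rep(fr$tau, ns))
  open <- c(rep(TRUE, ns), rep(FALSE, ns))
  cc <- c(ifelse(known_event, W * sq, 0) / ns, ifelse(surv, W * sq, 0) / ns)
  Gterm <- lsum(u, cc, open)

  phi_cond <- W * sq - bs + Gterm
  phi <- numeric(fr$n)
  phi[fr$ss] <- (fr$n / ns) * phi_cond
  list(estimate = bs, influence = phi, n = fr$n, n_at_risk = ns)
}

#' Time-dependent metric curve over a set of landmarks
#'
#' Computes AUC(s, s+w) or BS(s, s+w) at every landmark together with the
#' aligned full-sample influence values, the representation consumed by
#' [summary_metric()] and [compare_models()].
#'
#' @param risks long data frame with columns `id`, `LM` and `risk` (e.g.
#'   `risk_cause1` from [predict.penlm()], renamed or selected via
#'   `risk_col`), one row per subject at risk per landmark.
#' @param outcomes full test-sample outcomes (`id`, `time`, `status`) or an
#'   `lm_cohort`.
#' @param landmarks landmark times; default: all values of `risks$LM`.
#' @param window prediction window w.
#' @param metric `"auc"` or `"bs"`.
#' @param risk_col column of `risks` holding the predicted risk; defaults
#'   to `"risk"` or, if absent, `"risk_cause1"`.
#' @param include_competing passed to the landmark-level estimators.
#' @return An object of class `lm_metric_curve`: landmark estimates,
#'   per-landmark standard errors, and the n-by-|S| influence matrix.
#' @export
metric_curve <- function(risks, outcomes, window, landmarks = NULL,
                         metric = c("auc", "bs"), risk_col = NULL,
                         include_competing = TRUE) {
  metric <- match.arg(metric)
  if (inherits(outcomes, "lm_cohort")) outcomes <- outcomes$outcomes
  if (is.null(risk_col))
    risk_col <- if ("risk" %in% names(risks)) "risk" else "risk_cause1"
  if (!all(c("id", "LM", risk_col) %in% names(risks)))
    stop("risks must have columns id, LM and ", risk_col)
  if (is.null(landmarks)) landmarks <- sort(unique(risks$LM))
  n <- nrow(outcomes)
  est <- se <- numeric(length(landmarks))
  infl <- matrix(0, n, length(landmarks))
  fn <- if (metric == "auc") td_auc else td_brier
  for (li in seq_along(landmarks)) {
    s <- landmarks[li]
    rs <- risks[risks$LM == s, , drop = FALSE]
    rv <- rs[[risk_col]][match(outcomes$id, rs$id)]
    res <- fn(rv, outcomes, s, window, include_competing = include_competing)
    est[li] <- res$estimate
    infl[, li] <- res$influence
    se[li] <- sqrt(stats::var(res$influence) / n)
  }
  structure(list(metric = metric, landmarks = landmarks, window = window,
                 estimates = est, se = se, influence = infl, n = n,
                 ids = outcomes$id),
            class = "lm_metric_curve")
}

#' @export
print.lm_metric_curve <- function(x, ...) {
  cat("Time-dependent ", toupper(x$metric), "(s, s+w), w = ", x$window,
      ", n = ", x$n, "\n", sep = "")
  print(data.frame(LM = x$landmarks, estimate = x$estimates, se = x$se),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summary metric across landmarks with influence-function CI
#'
#' Averages the landmark-wise time-dependent metric into a single score
#' theta_bar_w and builds a Wald confidence interval from the multivariate
#' influence-function decomposition: the covariance of the landmark
#' estimates is Sigma[s,s'] = cov(phi(s), phi(s')) / n over the common test
#' sample, and SE(theta_bar) = sqrt(1' Sigma 1) / |S|.
#'
#' @param curve an `lm_metric_curve`.
#' @param level confidence level (default 0.95).
#' @return An object of class `lm_summary_metric` with `estimate`, `se`,
#'   `lower`, `upper` (truncated to \[0,1\]), `Sigma`, and the per-landmark
#'   table.
#' @export
summary_metric <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "lm_metric_curve"))
  if (any(!is.finite(curve$estimates)))
    stop("undefined landmark estimates at s = ",
         paste(curve$landmarks[!is.finite(curve$estimates)], collapse = ", "))
  L <- length(curve$landmarks)
  theta <- mean(curve$estimates)
  Sigma <- stats::cov(curve$influence) / curve$n
  Sigma <- (Sigma + t(Sigma)) / 2
  se <- sqrt(max(sum(Sigma), 0)) / L
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(theta - z * se, 0)
  hi <- min(theta + z * se, 1)
  per_lm <- data.frame(LM = curve$landmarks, estimate = curve$estimates,
                       se = curve$se,
                       lower = pmax(curve$estimates - z * curve$se, 0),
                       upper = pmin(curve$estimates + z * curve$se, 1))
  structure(list(metric = curve$metric, window = curve$window,
                 estimate = theta, se = se, lower = lo, upper = hi,
                 level = level, Sigma = Sigma, landmarks = per_lm,
                 n = curve$n),
            class = "lm_summary_metric")
}

#' @export
print.lm_summary_metric <- function(x, ...) {
  lab <- if (x$metric == "auc") "AUC" else "BS"
  cat("Summary ", lab, "_w (w = ", x$window, ") over ",
      nrow(x$landmarks), " landmarks, n = ", x$n, "\n", sep = "")
  cat(sprintf("  estimate %.4f  SE %.4f  %d%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, round(100 * x$level), x$lower, x$upper))
  invisible(x)
}

#' Test the difference in summary performance between two models
#'
#' Compares theta_bar_w of two models evaluated on the same test subjects
#' and landmarks: Delta = theta_A - theta_B, its standard error from the
#' per-subject averaged influence differences, a z statistic and a
#' two-sided normal p-value.  Landmark-wise comparisons (the traditional
#' per-landmark tests) are returned alongside.
#'
#' @param curve_a,curve_b `lm_metric_curve` objects of the same metric,
#'   computed on identical test subjects and landmarks.
#' @param level confidence level for the CI of the difference.
#' @return An object of class `lm_comparison` with `delta`, `se`, `z`,
#'   `p_value`, and a per-landmark data frame `landmarks`.
#' @export
compare_models <- function(curve_a, curve_b, level = 0.95) {
  stopifnot(inherits(curve_a, "lm_metric_curve"),
            inherits(curve_b, "lm_metric_curve"))
  if (!identical(curve_a$metric, curve_b$metric))
    stop("curves measure different metrics")
  if (!isTRUE(all.equal(curve_a$landmarks, curve_b$landmarks)) ||
      !identical(curve_a$window, curve_b$window))
    stop("curves use different landmarks or windows")
  if (curve_a$n != curve_b$n || !identical(curve_a$ids, curve_b$ids))
    stop("curves were computed on different test subjects")
  n <- curve_a$n
  delta <- mean(curve_a$estimates) - mean(curve_b$estimates)
  psi <- rowMeans(curve_a$influence - curve_b$influence)
  se <- sqrt(stats::var(psi) / n)
  if (se == 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else z <- delta / se
  p <- if (se == 0 && delta == 0) 1 else 2 * stats::pnorm(-abs(z))

  d_lm <- curve_a$estimates - curve_b$estimates
  dinf <- curve_a$influence - curve_b$influence
  se_lm <- sqrt(apply(dinf, 2L, stats::var) / n)
  z_lm <- ifelse(se_lm > 0, d_lm / se_lm, ifelse(d_lm == 0, 0, Inf * sign(d_lm)))
  p_lm <- ifelse(se_lm == 0 & d_lm == 0, 1, 2 * stats::pnorm(-abs(z_lm)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(metric = curve_a$metric, delta = delta, se = se, z = z,
                 p_value = p, level = level,
                 ci = c(delta - zq * se, delta + zq * se),
                 landmarks = data.frame(LM = curve_a$landmarks, delta = d_lm,
                                        se = se_lm, z = z_lm, p_value = p_lm),
                 n = n),
            class = "lm_comparison")
}

#' @export
print.lm_comparison <- function(x, ...) {
  lab <- if (x$metric == "auc") "AUC" else "BS"
  cat("Difference in summary ", lab, "_w between models\n", sep = "")
  cat(sprintf("  Delta %.4f  SE %.4f  z %.3f  p %.4g\n",
              x$delta, x$se, x$z, x$p_value))
  invisible(x)
}

#' Multiple-testing adjustment for landmark-wise p-values
#'
#' Adjusts a family of k landmark-specific p-values by the Bonferroni or
#' Benjamini-Hochberg step-up method; the family rejects when any adjusted
#' p-value falls below the significance level.
#'
#' @param p p-values in \[0,1\].
#' @param method `"bonferroni"` or `"BH"`.
#' @param level optional significance level; when given, the result carries
#'   an attribute `reject_family`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH"), level = NULL) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  adj <- stats::p.adjust(p, method = method)
  if (!is.null(level)) attr(adj, "reject_family") <- any(adj < level, na.rm = TRUE)
  adj
}
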