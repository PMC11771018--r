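#' Simulation scenario for landmark-form cohorts
#'
#' Defines one cell of the simulation design: cohorts carry three fixed
#' covariates (Z1, Z2 standard normal; Z3 Bernoulli(1/2)) and one
#' longitudinal covariate X updated at k equally spaced landmarks
#' s_m = m * lmi, following a linear drift X(s_m) = X(0) + rho*s_m + e_m
#' with X(0) ~ N(0,1) and e_m ~ N(0, sigma_e^2).  The event hazard is
#' piecewise constant between landmarks,
#' h(t) = h0 * exp((beta + beta_td * s_m)' (Z, X(s_m))) for t in
#' (s_m, s_{m+1}] (extending beyond the last landmark), so the data-
#' generating model itself has landmark form with a linear time-dependent
#' effect.  Censoring is independent exponential, with the rate calibrated
#' by root-finding on a pre-drawn event-time sample of size 1e5 so that the
#' censored fraction matches `censor_rate`.
#'
#' @param n training/test sample size.
#' @param k number of landmarks with longitudinal updates.
#' @param lmi landmark interval (time units).
#' @param censor_rate target censored fraction in \[0, 1).
#' @param beta main effects of (Z1, Z2, Z3, X).
#' @param beta_td linear time-dependent effects of the same covariates.
#' @param h0 baseline hazard rate.
#' @param rho drift of the longitudinal covariate per time unit.
#' @param sigma_e innovation SD of the longitudinal covariate.
#' @param window prediction window w.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 500, k = 3, lmi = 2, censor_rate = 0,
                         beta = c(0.5, -0.5, 0.3, 0.7),
                         beta_td = c(0, 0, 0, -0.05),
                         h0 = 0.05, rho = 0.2, sigma_e = 0.5, window = 5) {
  if (n < 2) stop("n must be >= 2")
  if (k < 1) stop("k must be >= 1")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("unattainable censor_rate: must lie in [0, 1)")
  if (length(beta) != 4L || length(beta_td) != 4L)
    stop("beta and beta_td must have length 4 (Z1, Z2, Z3, X)")
  if (h0 <= 0 || lmi <= 0 || window <= 0)
    stop("h0, lmi and window must be positive")
  structure(list(n = as.integer(n), k = as.integer(k), lmi = lmi,
                 censor_rate = censor_rate, beta = beta, beta_td = beta_td,
                 h0 = h0, rho = rho, sigma_e = sigma_e, window = window,
                 landmarks = (seq_len(k) - 1) * lmi),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario: n =", x$n, " k =", x$k, " lmi =", x$lmi,
      " censoring =", paste0(100 * x$censor_rate, "%"),
      " w =", x$window, "\n")
  invisible(x)
}

# raw draws (RNG must already be seeded by the caller); returns matrices
.sim_raw <- function(scn, n = scn$n) {
  k <- scn$k; s <- scn$landmarks
  Z1 <- stats::rnorm(n); Z2 <- stats::rnorm(n)
  Z3 <- stats::rbinom(n, 1L, 0.5)
  X0 <- stats::rnorm(n)
  X <- matrix(0, n, k)
  X[, 1L] <- X0
  if (k > 1L)
    for (m in 2:k)
      X[, m] <- X0 + scn$rho * s[m] + stats::rnorm(n, sd = scn$sigma_e)
  lp <- matrix(0, n, k)
  for (m in seq_len(k)) {
    b <- scn$beta + scn$beta_td * s[m]
    lp[, m] <- b[1L] * Z1 + b[2L] * Z2 + b[3L] * Z3 + b[4L] * X[, m]
  }
  Tev <- .invert_pwexp(lp, s, scn$h0)
  cr <- .censor_rate_lookup(scn)
  if (cr > 0) {
    C <- stats::rexp(n, rate = cr)
    time <- pmin(Tev, C)
    status <- as.integer(Tev <= C)
  } else {
    time <- Tev
    status <- rep(1L, n)
  }
  list(Z1 = Z1, Z2 = Z2, Z3 = Z3, X = X, Tev = Tev, time = time,
       status = status)
}

# piecewise-exponential event times by inversion of the cumulative hazard
.invert_pwexp <- function(lp, s, h0) {
  n <- nrow(lp); k <- ncol(lp)
  haz <- h0 * exp(lp)                      # per-interval rates
  widths <- diff(s)
  cumH <- matrix(0, n, k)                  # cumulative hazard at s_m
  if (k > 1L)
    for (m in 2:k) cumH[, m] <- cumH[, m - 1L] + haz[, m - 1L] * widths[m - 1L]
  E <- stats::rexp(n)
  Tev <- rep(NA_real_, n)
  for (m in seq_len(k)) {
    upper <- if (m < k) cumH[, m + 1L] else Inf
    hit <- is.na(Tev) & E >= cumH[, m] & E < upper
    Tev[hit] <- s[m] + (E[hit] - cumH[hit, m]) / haz[hit, m]
  }
  Tev
}

# calibrated exponential censoring rate, cached per scenario signature
.censor_rate_lookup <- function(scn) {
  if (scn$censor_rate == 0) return(0)
  key <- paste(c(scn$k, scn$lmi, scn$censor_rate, scn$beta, scn$beta_td,
                 scn$h0, scn$rho, scn$sigma_e), collapse = "|")
  hit <- .penlm_env$censor_rates[[key]]
  if (!is.null(hit)) return(hit)
  Ts <- .with_seed(48271L, {
    scn0 <- scn; scn0$censor_rate <- 0
    .sim_raw(scn0, n = 100000L)$Tev
  })
  f <- function(r) mean(1 - exp(-r * Ts)) - scn$censor_rate
  hi <- 1
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 4
  if (f(hi) < 0) stop("unattainable censor_rate ", scn$censor_rate)
  rate <- stats::uniroot(f, c(1e-12, hi), tol = 1e-10)$root
  if (is.null(.penlm_env$censor_rates)) .penlm_env$censor_rates <- list()
  .penlm_env$censor_rates[[key]] <- rate
  rate
}

#' Simulate a longitudinal cohort from a scenario
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional integer seed; the caller's RNG stream is restored
#'   afterwards, and the same seed reproduces the cohort exactly.
#' @param n override the scenario's sample size.
#' @return An `lm_cohort` with covariates Z1, Z2, Z3 (fixed) and X
#'   (longitudinal), measured at the scenario's landmarks while the subject
#'   is still under observation.
#' @export
simulate_cohort <- function(scenario, seed = NULL, n = scenario$n) {
  stopifnot(inherits(scenario, "sim_scenario"))
  raw <- .with_seed(seed, .sim_raw(scenario, n = n))
  .cohort_from_raw(raw, scenario)
}

.cohort_from_raw <- function(raw, scn) {
  n <- length(raw$time)
  out <- data.frame(id = seq_len(n), time = raw$time, status = raw$status)
  meas <- vector("list", scn$k)
  for (m in seq_len(scn$k)) {
    s <- scn$landmarks[m]
    keep <- which(raw$time >= s)
    meas[[m]] <- data.frame(id = keep, obs_time = s, Z1 = raw$Z1[keep],
                            Z2 = raw$Z2[keep], Z3 = raw$Z3[keep],
                            X = raw$X[keep, m])
  }
  meas <- do.call(rbind, meas)
  as_cohort(out, meas, n_causes = 1L)
}

# at-risk prediction frame straight from raw draws (one row per subject at
# risk per landmark), bypassing the measurement-table round trip
.pred_frame_raw <- function(raw, scn) {
  rows <- lapply(seq_len(scn$k), function(m) {
    s <- scn$landmarks[m]
    keep <- which(raw$time > s)
    data.frame(id = keep, LM = s, Z1 = raw$Z1[keep], Z2 = raw$Z2[keep],
               Z3 = raw$Z3[keep], X = raw$X[keep, m])
  })
  do.call(rbind, rows)
}

# ---- oracle truth -----------------------------------------------------------

# Precomputes everything about a large uncensored cohort that does not
# depend on the fitted model, so the population summary metric of many fits
# can be scored against the same Monte-Carlo sample.
.truth_cache <- function(scn, n_mc, seed, spec = td_spec(),
                         covariates = c("Z1", "Z2", "Z3", "X")) {
  raw <- .with_seed(seed, {
    scn0 <- scn; scn0$censor_rate <- 0
    .sim_raw(scn0, n = n_mc)
  })
  frames <- vector("list", scn$k)
  for (m in seq_len(scn$k)) {
    s <- scn$landmarks[m]
    keep <- which(raw$Tev > s)
    nd <- data.frame(LM = s, Z1 = raw$Z1[keep], Z2 = raw$Z2[keep],
                     Z3 = raw$Z3[keep], X = raw$X[keep, m])
    # the expanded design depends only on the cohort, not the fit: cache it
    Xe <- expand_design(nd, spec, covariates = covariates,
                        s0 = scn$landmarks[1L])$X
    frames[[m]] <- list(s = s, tau = s + scn$window,
                        D = as.numeric(raw$Tev[keep] <= s + scn$window),
                        Xe = Xe)
  }
  list(frames = frames, n_mc = n_mc)
}

# population summary AUC and BS of one fitted supermodel, via the cache
.true_summary_cached <- function(cache, fit) {
  cf <- fit$causes[[1L]]$coef
  bl <- fit$causes[[1L]]$baseline
  auc <- bs <- numeric(length(cache$frames))
  for (m in seq_along(cache$frames)) {
    fr <- cache$frames[[m]]
    lp <- as.numeric(fr$Xe %*% cf)
    in_win <- bl$time > fr$s & bl$time <= fr$tau
    pr <- if (any(in_win)) .window_risk_grid(lp, bl$hazard[in_win]) else
      rep(0, length(lp))
    D <- fr$D
    rk <- rank(pr)                      # average ranks: ties count one half
    n1 <- sum(D); n0 <- length(D) - n1
    if (n1 == 0 || n0 == 0) stop("degenerate truth sample at s = ", fr$s)
    auc[m] <- (sum(rk[D == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    bs[m] <- mean((D - pr)^2)
  }
  c(auc = mean(auc), bs = mean(bs))
}

#' Monte-Carlo population value of the summary metric for a fitted model
#'
#' Simulates a large uncensored cohort from the scenario, computes the
#' uncensored empirical time-dependent AUC or Brier score of the fitted
#' model at each landmark, and averages them: the "true" summary value this
#' model attains in the scenario's population, used to score CI coverage.
#'
#' @param scenario a [sim_scenario()].
#' @param fit a `penlm` fitted model.
#' @param metric `"auc"` or `"bs"`.
#' @param n_mc Monte-Carlo cohort size (>= 1e5 recommended).
#' @param seed seed for the Monte-Carlo draw.
#' @return The Monte-Carlo estimate of the population summary metric.
#' @export
true_summary <- function(scenario, fit, metric = c("auc", "bs"),
                         n_mc = 100000L, seed = 1L) {
  metric <- match.arg(metric)
  cache <- .truth_cache(scenario, n_mc, seed, spec = fit$spec,
                        covariates = fit$covariates)
  unname(.true_summary_cached(cache, fit)[metric])
}
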