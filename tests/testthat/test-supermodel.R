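library(survival)

test_that("stacked partial likelihood matches closed forms and brute force", {
  # single landmark, zero coefficients: each event contributes log(risk-set size)
  coh <- as_cohort(data.frame(id = 1:2, time = c(1, 9), status = c(1L, 0L)),
                   data.frame(id = 1:2, obs_time = 0, x = c(0.3, -0.1)))
  stk <- build_stack(coh, landmark_grid(0, 5))
  sp <- td_spec("const", list())
  expect_equal(neg_log_ipl(0, stk, sp), log(2))

  coh2 <- random_cohort(n = 25, seed = 4, censor = 0)
  stk2 <- build_stack(coh2, landmark_grid(0, 6))
  rs <- vapply(which(stk2$status == 1),
               function(i) sum(stk2$exit >= stk2$exit[i]), numeric(1))
  expect_equal(neg_log_ipl(c(0, 0), stk2, sp), sum(log(rs)))

  # pooled multi-landmark risk sets against the brute-force double loop
  coh3 <- random_cohort(n = 30, seed = 9)
  stk3 <- suppressWarnings(build_stack(coh3, landmark_grid(c(0, 1, 2), 4)))
  spec <- td_spec()
  cf <- c(0.4, -0.1, 0.2, 0.05, -0.3, 0.02)
  expect_equal(neg_log_ipl(cf, stk3, spec),
               brute_neg_log_ipl(cf, stk3, spec), tolerance = 1e-10)
})

test_that("unpenalized single-landmark supermodel is a standard Cox model", {
  coh <- random_cohort(n = 150, seed = 12)
  stk <- build_stack(coh, landmark_grid(0, 6))
  sp <- td_spec("const", list())
  fit <- penlm(stk, spec = sp, penalty = penalty_spec(0), causes = 1)
  cx <- coxph(Surv(exit, status == 1) ~ x + z, data = as.data.frame(stk),
              ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cx)), tolerance = 1e-4)

  bl <- breslow_baseline(fit)
  bh <- basehaz(cx, centered = FALSE)
  ref <- bh$hazard[match(bl$time, bh$time)]
  expect_equal(bl$cumhaz, ref, tolerance = 1e-6)
  expect_true(all(diff(bl$cumhaz) >= 0))
  expect_true(all(bl$cumhaz >= 0))

  # predictions agree through the cumulative hazard scale
  lp_mine <- predict(fit, coh, landmarks = 0, type = "lp")$lp_cause1
  lp_ref <- predict(cx, newdata = locf_covariates(coh, 0), reference = "zero")
  expect_equal(unname(lp_mine), unname(lp_ref), tolerance = 1e-4)
})

test_that("ridge fit matches glmnet on the standardized Cox objective", {
  skip_if_not_installed("glmnet")
  coh <- random_cohort(n = 200, seed = 7)
  stk <- build_stack(coh, landmark_grid(0, 6))
  sp <- td_spec("const", list())
  X <- expand_design(stk, sp)$X
  lam <- 15
  gn <- glmnet::glmnet(X, Surv(stk$exit, stk$status == 1), family = "cox",
                       alpha = 0, lambda = lam / nrow(stk),
                       standardize = TRUE, thresh = 1e-12)
  fit <- penlm(stk, spec = sp, penalty = penalty_spec(lam, mixing = 0),
               causes = 1)
  expect_equal(unname(coef(fit)), as.numeric(coef(gn)), tolerance = 1e-4)
})

test_that("penalization shrinks: ridge path monotone, lasso zeroes at lambda_max", {
  coh <- random_cohort(n = 120, seed = 15)
  stk <- suppressWarnings(build_stack(coh, landmark_grid(c(0, 1), 5)))
  norms <- vapply(c(0, 2, 10, 50), function(l)
    sqrt(sum(coef(penlm(stk, penalty = penalty_spec(l, mixing = 0),
                        causes = 1))^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))

  X <- expand_design(stk, td_spec())$X
  lmax <- penlm:::.lambda_max(X, stk$entry, stk$exit, stk$status, 1L, 1,
                              rep(1, ncol(X)))
  f_hi <- penlm(stk, penalty = penalty_spec(lmax * 1.0001, mixing = 1),
                causes = 1)
  expect_true(all(coef(f_hi) == 0))
  f_lo <- penlm(stk, penalty = penalty_spec(lmax * 0.5, mixing = 1),
                causes = 1)
  expect_true(any(coef(f_lo) != 0))

  # penalized objective at the optimum is never worse than at zero
  # (the penalty applies to the internally standardized coefficients)
  for (pen in list(penalty_spec(3, mixing = 1), penalty_spec(3, mixing = 0.4))) {
    f <- penlm(stk, penalty = pen, causes = 1)
    spec <- td_spec()
    bstd <- f$causes[[1]]$coef_std
    obj_fit <- neg_log_ipl(coef(f), stk, spec) +
      pen$lambda * sum(pen$mixing * abs(bstd) + (1 - pen$mixing) / 2 * bstd^2)
    expect_lte(obj_fit, neg_log_ipl(numeric(ncol(X)), stk, spec) + 1e-8)
  }
})

test_that("predictions are invariant to affine covariate rescaling at lambda = 0", {
  coh <- random_cohort(n = 100, seed = 31)
  grid <- landmark_grid(c(0, 1), 5)
  f1 <- penlm(suppressWarnings(build_stack(coh, grid)),
              penalty = penalty_spec(0), causes = 1)
  coh2 <- coh
  coh2$measurements$x <- 3 * coh2$measurements$x - 2
  f2 <- penlm(suppressWarnings(build_stack(coh2, grid)),
              penalty = penalty_spec(0), causes = 1)
  p1 <- suppressWarnings(predict(f1, coh, landmarks = c(0, 1)))
  p2 <- suppressWarnings(predict(f2, coh2, landmarks = c(0, 1)))
  expect_equal(p1$risk_cause1, p2$risk_cause1, tolerance = 1e-6)
})

test_that("cause-specific fitting treats other causes as censored", {
  coh <- competing_cohort(n = 250, seed = 21)
  grid <- landmark_grid(c(0, 1, 2), 4)
  stk <- build_stack(coh, grid)
  fit <- fit_csc(stk, penalty = penalty_spec(0))

  out2 <- coh$outcomes
  out2$status[out2$status == 2] <- 0L
  coh1 <- as_cohort(out2, coh$measurements, n_causes = 1)
  f1 <- penlm(build_stack(coh1, grid), penalty = penalty_spec(0), causes = 1)
  expect_identical(coef(fit)[, "cause1"], coef(f1))

  # exchangeable causes give matching coefficient magnitudes
  cohx <- competing_cohort(n = 4000, seed = 77, b1 = 0.5, b2 = 0.5,
                           cens_rate = 0)
  # make cause 2 depend on Z2 exactly as cause 1 depends on Z1
  stkx <- build_stack(cohx, landmark_grid(0, 4))
  fx <- fit_csc(stkx, spec = td_spec("const", list()),
                penalty = penalty_spec(0))
  cf <- coef(fx)
  expect_equal(cf["Z1", "cause1"], cf["Z2", "cause2"], tolerance = 0.12)
  expect_equal(cf["Z2", "cause1"], cf["Z1", "cause2"], tolerance = 0.12)

  expect_error(fit_csc(build_stack(random_cohort(30, seed = 2),
                                   landmark_grid(0, 5))), "J >= 2")
  # a requested cause with zero events errors by name
  expect_error(penlm(stk, causes = 3), "cause 3")
})

test_that("zero-coefficient baseline is the Nelson-Aalen estimator", {
  n <- 12
  set.seed(41)
  coh <- as_cohort(data.frame(id = 1:n, time = sort(runif(n, 1, 5)),
                              status = 1L),
                   data.frame(id = 1:n, obs_time = 0, x = rnorm(n)))
  stk <- build_stack(coh, landmark_grid(0, 10))
  fit <- penlm(stk, spec = td_spec("const", list()),
               penalty = penalty_spec(1e8, mixing = 1), causes = 1)
  expect_true(all(coef(fit) == 0))
  bl <- breslow_baseline(fit)
  expect_equal(bl$hazard, 1 / (n:1))
})

test_that("predicted risks follow the product-limit identities", {
  # J = 1 closed form: total window hazard 0.1 gives risk ~ 1 - exp(-0.1)
  n <- 80
  set.seed(52)
  coh <- as_cohort(data.frame(id = 1:n, time = rexp(n, 0.2) + 1e-3,
                              status = 1L),
                   data.frame(id = 1:n, obs_time = 0, x = rnorm(n, sd = 1e-8)))
  stk <- build_stack(coh, landmark_grid(0, 30))
  fit <- penlm(stk, spec = td_spec("const", list()),
               penalty = penalty_spec(1e8, mixing = 1), causes = 1)
  bl <- breslow_baseline(fit)
  tau <- bl$time[which.min(abs(bl$cumhaz - 0.1))]
  pr <- suppressWarnings(predict(fit, coh, landmarks = 0, window = tau))
  H <- bl$cumhaz[bl$time <= tau][sum(bl$time <= tau)]
  expect_equal(pr$risk_cause1[1], 1 - exp(-H), tolerance = 0.02)
  # all-zero coefficients: identical risk for every subject
  expect_equal(length(unique(round(pr$risk_cause1, 12))), 1L)

  # J = 2 conservation: F1 + F2 + S == 1 exactly
  coh2 <- competing_cohort(n = 200, seed = 33)
  fit2 <- fit_csc(build_stack(coh2, landmark_grid(c(0, 1), 4)),
                  penalty = penalty_spec(0))
  pr2 <- suppressWarnings(predict(fit2, coh2, landmarks = c(0, 1)))
  expect_true(all(abs(pr2$risk_cause1 + pr2$risk_cause2 + pr2$surv - 1) < 1e-10))
  expect_true(all(pr2$risk_cause1 >= 0 & pr2$risk_cause1 <= 1))
  expect_true(all(pr2$risk_cause1 + pr2$risk_cause2 <= 1 + 1e-12))
})

test_that("subject-grouped cross-validation is deterministic and sensible", {
  coh <- random_cohort(n = 90, seed = 18)
  stk <- suppressWarnings(build_stack(coh, landmark_grid(c(0, 1), 5)))
  expect_equal(cv_lambda(stk, lambda = 7, nfolds = 3, seed = 2)$lambda_min, 7)
  cv1 <- cv_lambda(stk, lambda = c(0.5, 2, 8), nfolds = 4, seed = 5)
  cv2 <- cv_lambda(stk, lambda = c(0.5, 2, 8), nfolds = 4, seed = 5)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$cvm, cv2$cvm)

  # pure-noise covariates: lambda* lands in the upper half of the grid
  hits <- 0L
  for (seed in 1:10) {
    set.seed(100 + seed)
    nn <- 60
    coh0 <- as_cohort(data.frame(id = 1:nn, time = rexp(nn, 0.3), status = 1L),
                      data.frame(id = 1:nn, obs_time = 0,
                                 x1 = rnorm(nn), x2 = rnorm(nn)))
    stk0 <- build_stack(coh0, landmark_grid(0, 8))
    grid_l <- exp(seq(log(20), log(0.02), length.out = 10))
    cv <- cv_lambda(stk0, spec = td_spec("const", list()), mixing = 1,
                    lambda = grid_l, nfolds = 4, seed = seed)
    if (cv$lambda_min >= sort(grid_l)[6]) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
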