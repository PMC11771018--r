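test_that("censoring Kaplan-Meier matches hand product-limit values", {
  # mixed sample of 8 printed times (censoring indicated by status 0)
  out <- data.frame(id = 1:8,
                    time = c(1, 2, 2, 3, 4, 5, 6, 7),
                    status = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  km <- censoring_km(out)
  # censoring events at t = 2 (1 of 7 at risk), 3 (1/5), 5 (1/3), 7 (1/1)
  expect_equal(km$time, c(2, 3, 5, 7))
  expect_equal(km$surv, cumprod(c(1 - 1/7, 1 - 1/5, 1 - 1/3, 0)))
  expect_equal(km_at(km, c(1.9, 2, 4.9, 7)),
               c(1, 6/7, 6/7 * 4/5, 0))
  expect_equal(km_at(km, 2, left = TRUE), 1)

  none <- censoring_km(data.frame(id = 1:4, time = 1:4, status = 1L))
  expect_equal(km_at(none, c(0.5, 10)), c(1, 1))
  all_c <- censoring_km(data.frame(id = 1:3, time = 2, status = 0L))
  expect_equal(km_at(all_c, 2), 0)
})

test_that("uncensored IPCW AUC equals the brute-force pair count", {
  set.seed(19)
  n <- 90
  out <- data.frame(id = 1:n, time = rexp(n, 0.2), status = 1L)
  out$status[sample(n, 20)] <- 2L
  risk <- round(plogis(rnorm(n)), 2)       # rounding forces some ties
  s <- 0.4; w <- 3; tau <- s + w
  a <- td_auc(risk, out, s, w)
  ss <- which(out$time > s)
  case <- ss[out$time[ss] <= tau & out$status[ss] == 1]
  ctrl <- ss[out$time[ss] > tau | out$status[ss] >= 2]
  num <- 0
  for (i in case) for (k in ctrl)
    num <- num + (risk[i] > risk[k]) + 0.5 * (risk[i] == risk[k])
  expect_equal(a$estimate, num / (length(case) * length(ctrl)),
               tolerance = 1e-12)

  # perfect separation and all-ties corner cases
  out2 <- data.frame(id = 1:6, time = c(1, 1.5, 9, 9, 9, 9), status = 1L)
  expect_equal(td_auc(c(.9, .8, .1, .2, .3, .15), out2, 0, 5)$estimate, 1)
  expect_equal(td_auc(rep(0.4, 6), out2, 0, 5)$estimate, 0.5)
  expect_error(td_auc(1:6 / 10, out2, 0, 0.5), "cases")
})

test_that("uncensored IPCW Brier score equals the plain mean squared error", {
  set.seed(23)
  n <- 70
  out <- data.frame(id = 1:n, time = rexp(n, 0.25), status = 1L)
  risk <- runif(n)
  s <- 0.2; w <- 2.5
  b <- td_brier(risk, out, s, w)
  ss <- which(out$time > s)
  D <- as.numeric(out$time[ss] <= s + w)
  expect_equal(b$estimate, mean((D - risk[ss])^2), tolerance = 1e-12)

  # risk equal to the outcome indicator scores zero
  expect_equal(td_brier(as.numeric(out$time <= s + w), out, s, w)$estimate, 0)
  # constant risk p against event fraction q
  p <- 0.3; q <- mean(D)
  expect_equal(td_brier(rep(p, n), out, s, w)$estimate,
               q * (1 - p)^2 + (1 - q) * p^2, tolerance = 1e-12)
})

test_that("censored toy Brier matches the hand-computed weighted sum", {
  out <- data.frame(id = 1:10,
                    time = c(1, 2, 2.5, 3, 4, 5, 6, 7, 8, 9),
                    status = c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L))
  risk <- seq(0.1, 0.95, length.out = 10)
  s <- 0; w <- 4.5; tau <- 4.5
  G <- function(t, strict = FALSE) {
    p <- 1
    for (vc in out$time[out$status == 0]) {
      inside <- if (strict) vc < t else vc <= t
      if (inside) p <- p * (1 - 1 / sum(out$time >= vc))
    }
    p
  }
  W <- ifelse(out$time <= tau & out$status == 1,
              1 / vapply(out$time, G, 1, strict = TRUE),
              ifelse(out$time > tau, 1 / G(tau), 0))
  D <- as.numeric(out$time <= tau & out$status == 1)
  expect_equal(td_brier(risk, out, s, w)$estimate,
               mean(W * (D - risk)^2), tolerance = 1e-12)
})

test_that("influence values are centered and reproduce single-landmark CIs", {
  set.seed(29)
  n <- 150
  out <- data.frame(id = 1:n, time = rexp(n, 0.2), status = 1L)
  out$status[rbinom(n, 1, 0.3) == 1] <- 0L
  risk <- plogis(0.8 * rnorm(n))
  for (s in c(0, 0.5)) {
    a <- td_auc(risk, out, s, 3)
    b <- td_brier(risk, out, s, 3)
    expect_lt(abs(mean(a$influence)), 1e-10)
    expect_lt(abs(mean(b$influence)), 1e-10)
  }
  rdf <- do.call(rbind, lapply(c(0, 0.5), function(s)
    data.frame(id = out$id[out$time > s], LM = s,
               risk = risk[out$time > s])))
  # |S| = 1 summary reduces exactly to the single-landmark metric
  cv1 <- metric_curve(rdf[rdf$LM == 0, ], out, window = 3, metric = "auc")
  sm1 <- summary_metric(cv1)
  a0 <- td_auc(risk, out, 0, 3)
  expect_identical(sm1$estimate, a0$estimate)
  expect_equal(sm1$se, sqrt(stats::var(a0$influence) / n))
  expect_equal(sm1$se, cv1$se[1])

  # identical influence across landmarks: summary SE equals landmark SE
  cv2 <- metric_curve(rdf, out, window = 3, metric = "auc")
  cv2$influence[, 2] <- cv2$influence[, 1]
  cv2$estimates[2] <- cv2$estimates[1]
  sm2 <- summary_metric(cv2)
  expect_equal(sm2$se, sqrt(stats::var(cv2$influence[, 1]) / n))
})

test_that("model comparisons are antisymmetric and self-comparison is null", {
  set.seed(37)
  n <- 120
  out <- data.frame(id = 1:n, time = rexp(n, 0.25), status = 1L)
  rA <- plogis(rnorm(n)); rB <- plogis(rnorm(n))
  mk <- function(r) metric_curve(
    do.call(rbind, lapply(c(0, 0.5), function(s)
      data.frame(id = out$id[out$time > s], LM = s, risk = r[out$time > s]))),
    out, window = 2, metric = "bs")
  ca <- mk(rA); cb <- mk(rB)
  self <- compare_models(ca, ca)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)
  ab <- compare_models(ca, cb); ba <- compare_models(cb, ca)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  cb1 <- cb
  cb1$landmarks <- cb1$landmarks[1]
  expect_error(compare_models(ca, cb1), "different landmarks")
})

test_that("p-value adjustment matches hand-computed Bonferroni and BH vectors", {
  expect_equal(as.numeric(adjust_pvalues(0.01, "bonferroni")), 0.01)
  expect_equal(as.numeric(adjust_pvalues(0.01, "BH")), 0.01)
  expect_equal(as.numeric(adjust_pvalues(c(0.01, 0.5, 0.2), "bonferroni")),
               c(0.03, 1, 0.6))
  expect_equal(as.numeric(adjust_pvalues(c(0.01, 0.02, 0.04), "BH")),
               c(0.03, 0.03, 0.04))
  adj <- adjust_pvalues(c(0.01, 0.8), "bonferroni", level = 0.05)
  expect_true(attr(adj, "reject_family"))
  expect_false(attr(adjust_pvalues(c(0.2, 0.8), "BH", level = 0.05),
                    "reject_family"))
  expect_error(adjust_pvalues(c(-0.1, 0.5)), "0,1")
})

test_that("random scores discriminate at chance level", {
  set.seed(43)
  n <- 4000
  out <- data.frame(id = 1:n, time = rexp(n, 0.3), status = 1L)
  a <- td_auc(runif(n), out, 0, 2)
  expect_lt(abs(a$estimate - 0.5), 0.03)
})
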