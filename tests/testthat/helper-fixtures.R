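# fixtures are generated in code; all randomness is locally seeded

# tiny deterministic cohort: 3 subjects, hand-written outcomes/measurements
toy_cohort <- function() {
  out <- data.frame(id = c("a", "b", "c"),
                    time = c(1.5, 8, 3),
                    status = c(1L, 1L, 0L))
  meas <- data.frame(id = c("a", "a", "b", "c"),
                     obs_time = c(0, 1, 0, 0),
                     x = c(1, 5, 2, -1),
                     z = c(0.5, 0.25, -0.5, 0))
  as_cohort(out, meas)
}

# random single-cause cohort with baseline + updated covariates
random_cohort <- function(n = 60, seed = 1, censor = 0.3, n_causes = 1L) {
  set.seed(seed)
  t_ev <- rexp(n, 0.15)
  cc <- if (censor > 0) rexp(n, 0.15 * censor / (1 - censor)) else
    rep(Inf, n)
  time <- pmin(t_ev, cc)
  cause <- if (n_causes > 1L) sample(seq_len(n_causes), n, replace = TRUE) else 1L
  status <- ifelse(censor > 0 & cc < t_ev, 0L, cause)
  out <- data.frame(id = seq_len(n), time = time, status = status)
  meas <- do.call(rbind, lapply(c(0, 1, 2), function(s) {
    keep <- which(time >= s)
    data.frame(id = keep, obs_time = s,
               x = rnorm(length(keep)), z = rbinom(length(keep), 1, 0.5))
  }))
  meas <- meas[order(meas$id, meas$obs_time), ]
  as_cohort(out, meas, n_causes = n_causes)
}

# two-cause cohort with baseline covariates and exponential cause hazards
competing_cohort <- function(n = 300, seed = 21, b1 = 0.6, b2 = -0.4,
                             cens_rate = 0.05) {
  set.seed(seed)
  Z1 <- rnorm(n); Z2 <- rnorm(n)
  h1 <- 0.10 * exp(b1 * Z1); h2 <- 0.08 * exp(b2 * Z2)
  t_ev <- rexp(n, h1 + h2)
  cause <- 1L + (runif(n) > h1 / (h1 + h2))
  cc <- if (cens_rate > 0) rexp(n, cens_rate) else Inf
  time <- pmin(t_ev, cc)
  status <- ifelse(t_ev <= cc, cause, 0L)
  as_cohort(data.frame(id = seq_len(n), time = time, status = status),
            data.frame(id = seq_len(n), obs_time = 0, Z1 = Z1, Z2 = Z2),
            n_causes = 2L)
}

# subset an lm_stack preserving its attributes
stack_subset <- function(stack, rows) {
  out <- stack[rows, , drop = FALSE]
  attr(out, "grid") <- attr(stack, "grid")
  attr(out, "covariates") <- attr(stack, "covariates")
  attr(out, "n_causes") <- attr(stack, "n_causes")
  class(out) <- class(stack)
  out
}

# brute-force negative stacked partial log-likelihood (double loop)
brute_neg_log_ipl <- function(coefs, stack, spec, cause = 1L) {
  eta <- as.numeric(expand_design(stack, spec)$X %*% coefs)
  val <- 0
  for (i in which(stack$status == cause)) {
    rs <- which(stack$entry < stack$exit[i] & stack$exit >= stack$exit[i])
    val <- val - (eta[i] - log(sum(exp(eta[rs]))))
  }
  val
}
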