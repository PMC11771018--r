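# Counting-process Cox machinery for the stacked pseudo-partial likelihood.
#
# Stacked rows are left-truncated intervals (entry, exit]; the risk set of an
# event at time t pools rows from ALL landmark datasets with entry < t <= exit,
# matching the double-sum denominator of the stacked pseudo-likelihood.
# Ties are handled with the Breslow approximation.
#
# All order statistics and interval lookups depend only on (entry, exit,
# event times), not on the coefficients, so they are precomputed once per fit
# and reused across iterations.

.cox_prep <- function(entry, exit, is_event) {
  tk <- sort(unique(exit[is_event]))
  dk <- as.numeric(tabulate(match(exit[is_event], tk), nbins = length(tk)))
  ord_entry <- order(entry); ord_exit <- order(exit)
  sn <- entry[ord_entry]; se <- exit[ord_exit]
  list(tk = tk, dk = dk, ord_entry = ord_entry, ord_exit = ord_exit,
       # S0(t) = sum_{entry < t} v - sum_{exit < t} v at each event time
       pos_entry = findInterval(tk, sn, left.open = TRUE),
       pos_exit = findInterval(tk, se, left.open = TRUE),
       # per-row accumulation sum_{entry_i < tk <= exit_i} q_k
       row_exit = findInterval(exit, tk),
       row_entry = findInterval(entry, tk),
       is_event = is_event, n = length(entry))
}

# loglik, per-row gradient and curvature at linear predictor eta
.cox_iter <- function(pp, eta, need_curv = TRUE) {
  M <- max(eta)
  ee <- exp(eta - M)
  cum_entry <- c(0, cumsum(ee[pp$ord_entry]))
  cum_exit <- c(0, cumsum(ee[pp$ord_exit]))
  S0 <- cum_entry[pp$pos_entry + 1L] - cum_exit[pp$pos_exit + 1L]
  if (any(S0 <= 0)) stop("empty or degenerate risk set in partial likelihood")
  loglik <- sum(eta[pp$is_event]) - sum(pp$dk * (log(S0) + M))

  # the recentering factor exp(M) cancels between exp(eta) and the risk-set
  # sums, so gradient and curvature are assembled on the stable scale
  q1 <- pp$dk / S0
  Q1 <- c(0, cumsum(q1))
  acc1 <- Q1[pp$row_exit + 1L] - Q1[pp$row_entry + 1L]
  g <- as.numeric(pp$is_event) - ee * acc1
  out <- list(loglik = loglik, g = g, S0 = S0 * exp(M))
  if (need_curv) {
    q2 <- pp$dk / S0^2
    Q2 <- c(0, cumsum(q2))
    acc2 <- Q2[pp$row_exit + 1L] - Q2[pp$row_entry + 1L]
    out$wdiag <- pmax(ee * acc1 - ee^2 * acc2, 0)
  }
  out
}

#' Negative stacked partial log-likelihood
#'
#' Evaluates -log ipl*, the negative log pseudo-partial likelihood of the
#' landmark supermodel for one cause: the sum over cause-`cause` event rows
#' of the log ratio of exp(linear predictor) to its sum over all stacked
#' rows at risk (entry < event time <= exit, risk sets pooled across
#' landmark datasets).  Rows of other causes count as censored at their exit.
#'
#' @param coefs coefficient vector over the expanded design columns.
#' @param stack an `lm_stack`.
#' @param spec an `lm_td_spec`; the design is built with [expand_design()].
#' @param cause event code whose likelihood is evaluated.
#' @param design optional precomputed design matrix (bypasses `spec`).
#' @return A single nonnegative number.
#' @export
neg_log_ipl <- function(coefs, stack, spec = td_spec(), cause = 1L,
                        design = NULL) {
  X <- if (is.null(design)) expand_design(stack, spec)$X else design
  if (length(coefs) != ncol(X))
    stop("coefs has length ", length(coefs), ", design has ", ncol(X), " columns")
  eta <- as.numeric(X %*% coefs)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  is_event <- stack$status == cause
  if (!any(is_event)) stop("no events of cause ", cause, " in the stack")
  pp <- .cox_prep(stack$entry, stack$exit, is_event)
  ll <- .cox_iter(pp, eta, need_curv = FALSE)$loglik
  if (!is.finite(ll)) stop("non-finite pseudo-partial likelihood")
  -ll
}

# Elastic-net penalty value (on whatever scale beta is given)
.pen_value <- function(beta, lambda, mixing, pf) {
  lambda * sum(pf * (mixing * abs(beta) + (1 - mixing) / 2 * beta^2))
}

# Penalized Cox fit for one cause by IRLS + cyclic coordinate descent on the
# standardized design.  Returns coefficients on the original scale.
.fit_pencox_core <- function(X, entry, exit, status, cause, lambda, mixing,
                             pf, tol = 1e-7, max_iter = 10000L) {
  is_event <- status == cause
  if (!any(is_event)) stop("no events of cause ", cause, " in the stack")
  p <- ncol(X)
  ctr <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  active <- which(sdv > 1e-12)
  beta_full <- numeric(p)
  names(beta_full) <- colnames(X)
  if (length(active) == 0L)
    return(list(coef = beta_full, coef_std = beta_full, iter = 0L,
                converged = TRUE, lambda = lambda, mixing = mixing,
                center = ctr, scale = sdv, neg_log_ipl = NA_real_))
  Xs <- sweep(sweep(X[, active, drop = FALSE], 2L, ctr[active]),
              2L, sdv[active], "/")
  Xs2 <- Xs^2
  pfa <- pf[active]
  pp <- .cox_prep(entry, exit, is_event)

  beta <- numeric(length(active))
  eta <- rep(0, nrow(Xs))
  suff <- .cox_iter(pp, eta)
  obj <- -suff$loglik + .pen_value(beta, lambda, mixing, pfa)
  sweeps <- 0L
  converged <- FALSE
  delta_outer <- Inf

  for (outer in seq_len(200L)) {
    w <- suff$wdiag
    use <- w > 1e-12
    z <- eta
    z[use] <- eta[use] + suff$g[use] / w[use]
    w[!use] <- 0

    if (lambda * mixing * max(pfa) == 0) {
      # no L1 component: the coordinate-descent fixpoint of the penalized
      # weighted least-squares subproblem is available in closed form
      sweeps <- sweeps + 1L
      A <- crossprod(Xs, Xs * w)
      diag(A) <- diag(A) + lambda * (1 - mixing) * pfa + 1e-12
      beta_new <- as.numeric(solve(A, crossprod(Xs, w * z)))
    } else {
      wx2 <- as.numeric(crossprod(Xs2, w))
      r <- (z - eta) * w                      # weighted residual w*(z - eta)
      beta_new <- beta
      for (inner in seq_len(1000L)) {
        sweeps <- sweeps + 1L
        delta_max <- 0
        for (j in seq_along(beta_new)) {
          bj <- beta_new[j]
          gj <- sum(Xs[, j] * r) + wx2[j] * bj
          thr <- lambda * mixing * pfa[j]
          den <- wx2[j] + lambda * (1 - mixing) * pfa[j]
          bn <- if (den > 0) sign(gj) * max(abs(gj) - thr, 0) / den else 0
          if (bn != bj) {
            r <- r - Xs[, j] * ((bn - bj) * w)
            beta_new[j] <- bn
            delta_max <- max(delta_max, abs(bn - bj) / max(1, abs(bn)))
          }
        }
        if (delta_max < tol || sweeps >= max_iter) break
      }
    }

    # step acceptance with halving: the quadratic approximation is not
    # guaranteed to decrease the exact penalized objective
    step_ok <- FALSE
    for (half in 0:12) {
      beta_try <- beta + (beta_new - beta) / 2^half
      eta_try <- as.numeric(Xs %*% beta_try)
      if (max(abs(eta_try)) > 250) next     # overflow guard; shrink further
      suff_try <- .cox_iter(pp, eta_try)
      obj_try <- -suff_try$loglik + .pen_value(beta_try, lambda, mixing, pfa)
      if (is.finite(obj_try) && obj_try <= obj + 1e-10 * (1 + abs(obj))) {
        step_ok <- TRUE
        break
      }
    }
    if (!step_ok) { converged <- TRUE; break }  # no further descent possible
    delta_outer <- max(abs(beta_try - beta) / pmax(1, abs(beta_try)))
    beta <- beta_try; eta <- eta_try; suff <- suff_try; obj <- obj_try
    if (max(abs(beta)) > 60)
      stop("coefficients diverging (possible separation); ",
           "refit with a positive penalty lambda")
    if (delta_outer < tol) { converged <- TRUE; break }
    if (sweeps >= max_iter) break
  }
  if (!converged)
    stop("coordinate descent did not converge at lambda = ", lambda,
         " (last relative change ", signif(delta_outer, 3), ")")

  beta_full[active] <- beta / sdv[active]
  beta_std <- numeric(p); names(beta_std) <- colnames(X)
  beta_std[active] <- beta
  list(coef = beta_full, coef_std = beta_std, iter = sweeps,
       converged = converged, lambda = lambda, mixing = mixing,
       center = ctr, scale = sdv, neg_log_ipl = -suff$loglik)
}

# Breslow increments dH(tk) = dk / sum_{at risk} exp(eta), pooled risk sets
.breslow_core <- function(eta, entry, exit, status, cause) {
  is_event <- status == cause
  if (!any(is_event))
    return(list(time = numeric(), hazard = numeric(), cumhaz = numeric()))
  pp <- .cox_prep(entry, exit, is_event)
  it <- .cox_iter(pp, eta, need_curv = FALSE)
  dH <- pp$dk / it$S0
  list(time = pp$tk, hazard = dH, cumhaz = cumsum(dH))
}

# smallest lambda that zeroes every penalized coefficient (gradient at 0 on
# the standardized design); alpha columns included per their penalty factors
.lambda_max <- function(X, entry, exit, status, cause, mixing, pf) {
  is_event <- status == cause
  ctr <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  active <- which(sdv > 1e-12 & pf > 0)
  if (!length(active)) return(1)
  Xs <- sweep(sweep(X[, active, drop = FALSE], 2L, ctr[active]),
              2L, sdv[active], "/")
  pp <- .cox_prep(entry, exit, is_event)
  it <- .cox_iter(pp, rep(0, nrow(Xs)), need_curv = FALSE)
  grad <- as.numeric(crossprod(Xs, it$g))
  max(abs(grad) / pf[active]) / max(mixing, 1e-3)
}
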