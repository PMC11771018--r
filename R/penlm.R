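#' Elastic-net penalty specification
#'
#' @param lambda nonnegative penalty strength; 0 gives the unpenalized
#'   supermodel.
#' @param mixing elastic-net mixing in \[0,1\]: 1 = LASSO, 0 = ridge.
#' @param penalty_factors optional per-column nonnegative multipliers over
#'   the expanded design (recycled); the default 1 penalizes covariate and
#'   landmark-time (alpha) columns alike.  Set the alpha entries to 0 to
#'   exempt the landmark main effects.
#' @return An object of class `lm_penalty`.
#' @export
penalty_spec <- function(lambda = 0, mixing = 1, penalty_factors = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single nonnegative number")
  if (!is.numeric(mixing) || length(mixing) != 1L || mixing < 0 || mixing > 1)
    stop("mixing must be in [0, 1]")
  if (!is.null(penalty_factors) && any(penalty_factors < 0))
    stop("penalty_factors must be nonnegative")
  structure(list(lambda = lambda, mixing = mixing,
                 penalty_factors = penalty_factors),
            class = "lm_penalty")
}

#' Fit a penalized landmark supermodel
#'
#' Fits, for each requested cause, a Cox-type model to the stacked landmark
#' dataset by maximizing the elastic-net penalized log pseudo-partial
#' likelihood.  Covariate effects vary smoothly with landmark time through
#' the basis in `spec` (main plus time-dependent effects), the landmark main
#' effect alpha(s) is carried by the alpha columns, and risk sets are pooled
#' across landmark datasets as left-truncated counting-process intervals.
#' With several causes each model treats the other causes as censored
#' (cause-specific hazards); with a single landmark, constant basis and
#' `lambda = 0` the supermodel reduces to a standard Cox model.
#'
#' Columns are standardized to unit variance internally before penalization
#' and coefficients are reported back on the original covariate scale.
#' Optimization is cyclic coordinate descent inside an iteratively
#' reweighted least-squares loop, with step halving so the penalized
#' objective decreases monotonically.  Breslow baseline cumulative hazards
#' are estimated for every cause at the fitted coefficients.
#'
#' @param stack an `lm_stack` from [build_stack()].
#' @param spec an `lm_td_spec`; defaults to main + linear time-dependent
#'   covariate effects and a quadratic landmark main effect.
#' @param penalty an `lm_penalty`; defaults to no penalization.
#' @param causes `"all"` (default) or an integer vector of cause codes.
#' @param covariates covariate columns to include; defaults to all
#'   covariates on the stack.
#' @param tol relative coefficient-change convergence tolerance.
#' @param max_iter cap on coordinate-descent sweeps.
#' @return An object of class `penlm`; see [predict.penlm()],
#'   [coef.penlm()], [breslow_baseline()].
#' @export
penlm <- function(stack, spec = td_spec(), penalty = penalty_spec(),
                  causes = "all", covariates = NULL,
                  tol = 1e-7, max_iter = 10000L) {
  stopifnot(inherits(spec, "lm_td_spec"), inherits(penalty, "lm_penalty"))
  grid <- attr(stack, "grid")
  if (is.null(grid)) stop("stack carries no landmark grid attribute")
  if (is.null(covariates)) covariates <- attr(stack, "covariates")
  n_causes <- attr(stack, "n_causes")
  if (is.null(n_causes)) n_causes <- max(1L, max(stack$status))
  if (identical(causes, "all")) causes <- seq_len(n_causes)
  causes <- as.integer(causes)
  for (j in causes)
    if (!any(stack$status == j))
      stop("no events of cause ", j, " in the stack; cannot fit its model")

  des <- expand_design(stack, spec, covariates = covariates,
                       s0 = grid$landmarks[1L])
  p <- ncol(des$X)
  pf <- penalty$penalty_factors
  pf <- if (is.null(pf)) rep(1, p) else rep_len(pf, p)

  fits <- vector("list", length(causes))
  names(fits) <- paste0("cause", causes)
  for (ci in seq_along(causes)) {
    j <- causes[ci]
    f <- .fit_pencox_core(des$X, stack$entry, stack$exit, stack$status, j,
                          lambda = penalty$lambda, mixing = penalty$mixing,
                          pf = pf, tol = tol, max_iter = max_iter)
    eta <- as.numeric(des$X %*% f$coef)
    f$baseline <- .breslow_core(eta, stack$entry, stack$exit, stack$status, j)
    f$cause <- j
    fits[[ci]] <- f
  }

  structure(list(causes = fits, cause_codes = causes, map = des$map,
                 spec = spec, grid = grid, penalty = penalty,
                 covariates = covariates, n_causes = n_causes,
                 call = match.call()),
            class = "penlm")
}

#' Cause-specific Cox supermodel for competing risks
#'
#' Thin wrapper around [penlm()] that requires at least two competing
#' causes and fits one penalized supermodel per cause.
#'
#' @inheritParams penlm
#' @return A `penlm` object with one component per cause.
#' @export
fit_csc <- function(stack, spec = td_spec(), penalty = penalty_spec(),
                    covariates = NULL, tol = 1e-7, max_iter = 10000L) {
  n_causes <- attr(stack, "n_causes")
  if (is.null(n_causes)) n_causes <- max(1L, max(stack$status))
  if (n_causes < 2L)
    stop("cause-specific modelling needs J >= 2 competing causes; ",
         "use penlm() for a single cause")
  penlm(stack, spec = spec, penalty = penalty, causes = "all",
        covariates = covariates, tol = tol, max_iter = max_iter)
}

#' Breslow baseline cumulative hazards of a fitted supermodel
#'
#' @param fit a `penlm` object.
#' @param cause cause code; defaults to all fitted causes.
#' @return A list per cause with elements `time`, `hazard` (increments) and
#'   `cumhaz`; the cumulative hazard is a nondecreasing step function
#'   starting at 0.
#' @export
breslow_baseline <- function(fit, cause = NULL) {
  stopifnot(inherits(fit, "penlm"))
  if (is.null(cause)) cause <- fit$cause_codes
  out <- lapply(cause, function(j) {
    comp <- fit$causes[[match(j, fit$cause_codes)]]
    if (is.null(comp)) stop("cause ", j, " was not fitted")
    comp$baseline
  })
  names(out) <- paste0("cause", cause)
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
coef.penlm <- function(object, cause = NULL, ...) {
  if (is.null(cause)) cause <- object$cause_codes
  cf <- vapply(cause, function(j)
    object$causes[[match(j, object$cause_codes)]]$coef,
    numeric(nrow(object$map)))
  cf <- matrix(cf, nrow = nrow(object$map))
  dimnames(cf) <- list(object$map$column, paste0("cause", cause))
  if (length(cause) == 1L) drop(cf) else cf
}

#' @export
print.penlm <- function(x, ...) {
  cat("Penalized landmark supermodel\n")
  print(x$grid)
  cat("  causes fitted: ", paste(x$cause_codes, collapse = ", "),
      "; penalty: lambda = ", x$penalty$lambda,
      ", mixing = ", x$penalty$mixing, "\n", sep = "")
  cat("  design columns:", nrow(x$map), " (",
      sum(x$map$type == "main"), " main, ", sum(x$map$type == "td"),
      " time-dependent, ", sum(x$map$type == "alpha"), " alpha)\n", sep = "")
  invisible(x)
}

#' @export
summary.penlm <- function(object, ...) {
  cf <- coef(object)
  cf <- if (is.matrix(cf)) cf else matrix(cf, ncol = 1,
                                          dimnames = list(names(cf), "cause1"))
  tab <- data.frame(object$map, cf, check.names = FALSE)
  structure(list(coefficients = tab, grid = object$grid,
                 penalty = object$penalty,
                 iterations = vapply(object$causes, `[[`, 0L, "iter")),
            class = "summary.penlm")
}

#' @export
print.summary.penlm <- function(x, ...) {
  cat("Penalized landmark supermodel -- coefficient table\n")
  print(x$grid)
  cat("lambda =", x$penalty$lambda, " mixing =", x$penalty$mixing, "\n\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# step-function evaluation of a baseline cumulative hazard at times t
.cumhaz_at <- function(bl, t) {
  idx <- findInterval(t, bl$time)
  c(0, bl$cumhaz)[idx + 1L]
}

# Single-cause window risk for many subjects sharing one baseline: the
# product-limit risk 1 - prod_k(1 - exp(lp) dH_k) is a monotone smooth
# function of the linear predictor, so it is evaluated on an lp grid and
# linearly interpolated (grid fine enough that the interpolation error is
# far below Monte-Carlo noise; ranking of subjects is preserved exactly)
.window_risk_grid <- function(lp, dH, grid_n = 512L) {
  r <- range(lp)
  if (r[1L] == r[2L]) {
    f1 <- 1 - prod(1 - exp(r[1L]) * dH)
    return(rep(min(max(f1, 0), 1), length(lp)))
  }
  gl <- seq(r[1L], r[2L], length.out = grid_n)
  eg <- exp(gl)
  Fg <- 1 - vapply(eg, function(e) prod(1 - e * dH), numeric(1L))
  Fg <- pmin(pmax(Fg, 0), 1)
  stats::approx(gl, Fg, xout = lp, rule = 2)$y
}

#' Dynamic w-year risk predictions from a fitted supermodel
#'
#' For each subject and landmark s, computes the predicted cumulative
#' incidence of each cause over (s, s + w]: the per-cause linear predictor
#' lp_j(s) = alpha_j(s) + beta_j(s)'Z(s) is held fixed over the window and
#' combined with the Breslow baselines through the discrete product-limit
#' (Aalen-Johansen) form, so that predicted cause-specific risks and
#' event-free survival sum exactly to one.
#'
#' @param object a `penlm` fit.
#' @param newdata an `lm_cohort` (covariates are carried forward to each
#'   landmark for subjects still at risk) or a data frame with columns `id`,
#'   `LM` and the model covariates.
#' @param landmarks landmark times at which to predict; defaults to the
#'   fitted grid (required when `newdata` is a cohort).
#' @param window prediction window; defaults to the fitted grid's.
#' @param type `"risk"` (cumulative incidence) or `"lp"` (linear predictor).
#' @param ... unused.
#' @return A long data frame: `id`, `LM`, one column per cause
#'   (`risk_cause1`, ... or `lp_cause1`, ...), and for `type = "risk"` the
#'   event-free survival `surv`.
#' @export
predict.penlm <- function(object, newdata, landmarks = NULL, window = NULL,
                          type = c("risk", "lp"), ...) {
  type <- match.arg(type)
  if (is.null(window)) window <- object$grid$window
  if (inherits(newdata, "lm_cohort")) {
    if (is.null(landmarks)) landmarks <- object$grid$landmarks
    rows <- lapply(landmarks, function(s) {
      ids <- newdata$outcomes$id[newdata$outcomes$time > s]
      if (!length(ids)) return(NULL)
      z <- locf_covariates(newdata, s, ids = ids)
      data.frame(id = z$id, LM = s, z[object$covariates], check.names = FALSE)
    })
    newdata <- do.call(rbind, rows)
  } else {
    newdata <- as.data.frame(newdata)
    if (!all(c("id", "LM") %in% names(newdata)))
      stop("newdata must have columns id and LM")
    miss <- setdiff(object$covariates, names(newdata))
    if (length(miss))
      stop("newdata is missing model covariates: ", paste(miss, collapse = ", "))
    if (!is.null(landmarks)) newdata <- newdata[newdata$LM %in% landmarks, ]
  }
  if (is.null(newdata) || nrow(newdata) == 0L)
    stop("no subjects at risk at the requested landmarks")
  srange <- range(object$grid$landmarks)
  if (any(newdata$LM < srange[1L] - 1e-9 | newdata$LM > srange[2L] + 1e-9))
    warning("predicting at landmarks outside the fitted range [",
            srange[1L], ", ", srange[2L], "]")

  des <- expand_design(newdata, object$spec, covariates = object$covariates,
                       s0 = object$grid$landmarks[1L])
  lp <- vapply(object$causes, function(f) as.numeric(des$X %*% f$coef),
               numeric(nrow(newdata)))
  lp <- matrix(lp, nrow = nrow(newdata))
  colnames(lp) <- names(object$causes)

  if (type == "lp") {
    out <- data.frame(id = newdata$id, LM = newdata$LM)
    out[paste0("lp_", names(object$causes))] <- as.data.frame(lp)
    return(out)
  }

  J <- length(object$causes)
  res_risk <- matrix(NA_real_, nrow(newdata), J)
  res_surv <- rep(NA_real_, nrow(newdata))
  max_event <- max(vapply(object$causes,
                          function(f) if (length(f$baseline$time)) max(f$baseline$time) else -Inf,
                          numeric(1L)))
  for (s in unique(newdata$LM)) {
    sel <- which(newdata$LM == s)
    tau <- s + window
    if (tau > max_event + 1e-9)
      warning("prediction window (", s, ", ", tau, "] extends beyond the last ",
              "observed event time ", max_event,
              "; risk computed on available support", call. = FALSE)
    times <- sort(unique(unlist(lapply(object$causes, function(f)
      f$baseline$time[f$baseline$time > s & f$baseline$time <= tau]))))
    if (!length(times)) { res_risk[sel, ] <- 0; res_surv[sel] <- 1; next }
    dH <- vapply(object$causes, function(f) {
      idx <- match(times, f$baseline$time)
      ifelse(is.na(idx), 0, f$baseline$hazard[idx])
    }, numeric(length(times)))
    dH <- matrix(dH, nrow = length(times))

    elp <- exp(lp[sel, , drop = FALSE])
    if (J == 1L && length(sel) > 200L) {
      res_risk[sel, 1L] <- .window_risk_grid(lp[sel, 1L], dH[, 1L])
      res_surv[sel] <- 1 - res_risk[sel, 1L]
    } else {
      haz <- lapply(seq_len(J), function(j) outer(elp[, j], dH[, j]))
      Delta <- Reduce(`+`, haz)
      Sfac <- 1 - Delta
      Sminus <- cbind(1, t(apply(Sfac, 1L, cumprod)))[, seq_len(length(times)),
                                                      drop = FALSE]
      for (j in seq_len(J)) res_risk[sel, j] <- rowSums(haz[[j]] * Sminus)
      res_surv[sel] <- apply(Sfac, 1L, prod)
    }
  }
  out <- data.frame(id = newdata$id, LM = newdata$LM)
  out[paste0("risk_", names(object$causes))] <- as.data.frame(res_risk)
  out$surv <- res_surv
  out
}

#' Cross-validate the penalty strength
#'
#' Subject-grouped cross-validation of lambda for one cause: folds are
#' formed on subject ids so all landmark rows of a subject share a fold,
#' and each fold's validation deviance is the Verweij-van Houwelingen
#' cross-validated pseudo-partial-likelihood deviance
#' -2 (l_full(beta_-k) - l_-k(beta_-k)).
#'
#' @param stack an `lm_stack`.
#' @param spec an `lm_td_spec`.
#' @param mixing elastic-net mixing parameter.
#' @param lambda optional decreasing grid; defaults to 100 log-spaced values
#'   from the data-derived lambda_max down four decades.
#' @param nfolds number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param cause cause code.
#' @param covariates,penalty_factors as in [penlm()].
#' @return list with `lambda_min` (ties broken towards the larger lambda),
#'   `lambda`, `cvm` (mean validation deviance) and `nfolds_used`.
#' @export
cv_lambda <- function(stack, spec = td_spec(), mixing = 1, lambda = NULL,
                      nfolds = 10L, seed = 1L, cause = 1L,
                      covariates = NULL, penalty_factors = NULL) {
  if (nfolds < 2L) stop("nfolds must be >= 2")
  grid <- attr(stack, "grid")
  if (is.null(covariates)) covariates <- attr(stack, "covariates")
  des <- expand_design(stack, spec, covariates = covariates,
                       s0 = grid$landmarks[1L])
  p <- ncol(des$X)
  pf <- if (is.null(penalty_factors)) rep(1, p) else rep_len(penalty_factors, p)

  if (is.null(lambda)) {
    lmax <- .lambda_max(des$X, stack$entry, stack$exit, stack$status, cause,
                        mixing, pf)
    lambda <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100L))
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  if (!length(lambda)) stop("lambda grid is empty")

  ids <- unique(stack$id)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(nfolds), length(ids)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  names(fold_of) <- as.character(ids)
  row_fold <- fold_of[as.character(stack$id)]

  ll_at <- function(rows, beta) {
    is_event <- stack$status[rows] == cause
    if (!any(is_event)) return(NA_real_)
    pp <- .cox_prep(stack$entry[rows], stack$exit[rows], is_event)
    .cox_iter(pp, as.numeric(des$X[rows, , drop = FALSE] %*% beta),
              need_curv = FALSE)$loglik
  }

  dev <- matrix(NA_real_, nfolds, length(lambda))
  used <- 0L
  for (k in seq_len(nfolds)) {
    tr <- which(row_fold != k)
    va <- which(row_fold == k)
    if (!any(stack$status[va] == cause)) {
      warning("fold ", k, " has no cause-", cause, " events; skipped")
      next
    }
    used <- used + 1L
    for (li in seq_along(lambda)) {
      f <- .fit_pencox_core(des$X[tr, , drop = FALSE], stack$entry[tr],
                            stack$exit[tr], stack$status[tr], cause,
                            lambda = lambda[li], mixing = mixing, pf = pf)
      dev[k, li] <- -2 * (ll_at(seq_len(nrow(stack)), f$coef) - ll_at(tr, f$coef))
    }
  }
  if (used == 0L) stop("every fold lacked cause-", cause, " events")
  cvm <- colMeans(dev, na.rm = TRUE)
  best <- which(cvm <= min(cvm) + 1e-12)
  list(lambda_min = lambda[min(best)], lambda = lambda, cvm = cvm,
       nfolds_used = used)
}
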