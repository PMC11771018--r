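#' Landmark grid
#'
#' A set of prediction-origin times ("landmarks") together with the risk
#' prediction window w: at each landmark s the model predicts the
#' probability of an event in (s, s + w].
#'
#' @param landmarks strictly increasing, nonnegative landmark times.
#' @param window positive prediction window w, in the same time units as the
#'   landmarks.
#' @return An object of class `lm_grid`.
#' @export
landmark_grid <- function(landmarks, window) {
  landmarks <- as.numeric(landmarks)
  if (length(landmarks) < 1L || any(!is.finite(landmarks)))
    stop("landmarks must be a nonempty numeric vector")
  if (is.unsorted(landmarks, strictly = TRUE))
    stop("landmarks must be strictly increasing")
  if (landmarks[1L] < 0) stop("the first landmark must be >= 0")
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) || window <= 0)
    stop("window must be a positive number")
  structure(list(landmarks = landmarks, window = as.numeric(window)),
            class = "lm_grid")
}

#' @export
print.lm_grid <- function(x, ...) {
  cat("Landmark grid: s = {", paste(x$landmarks, collapse = ", "),
      "}, window w = ", x$window, "\n", sep = "")
  invisible(x)
}

#' Landmark-time effect specification
#'
#' Declares the basis functions of landmark time s used by the supermodel:
#' covariate effects are beta(s) = sum_m b_m f_m(s) over `beta_basis`
#' (which must contain the constant, giving the main effect), and the
#' landmark main effect is alpha(s) = sum_q a_q g_q(s) over `alpha_basis`.
#' To keep the baseline hazard identifiable, alpha-basis functions are
#' evaluated in (s - s0) so that alpha vanishes at the first landmark.
#'
#' @param beta_basis character vector among `"const"`, `"linear"`,
#'   `"quadratic"`, or a named list of functions of s.  Must include the
#'   constant.  Default `c("const","linear")`: a main plus linear
#'   time-dependent effect per covariate.
#' @param alpha_basis character vector among `"linear"`, `"quadratic"` (no
#'   constant: the baseline hazard absorbs the level), or a named list of
#'   functions of (s - s0) vanishing at 0.  Default `c("linear","quadratic")`.
#' @return An object of class `lm_td_spec`.
#' @export
td_spec <- function(beta_basis = c("const", "linear"),
                    alpha_basis = c("linear", "quadratic")) {
  base_fns <- list(const = function(s) rep(1, length(s)),
                   linear = function(s) s,
                   quadratic = function(s) s^2)
  pick <- function(x, allow_const) {
    if (is.character(x)) {
      bad <- setdiff(x, names(base_fns))
      if (length(bad)) stop("unknown basis name: ", paste(bad, collapse = ", "))
      fns <- base_fns[x]
    } else if (is.list(x)) {
      if (is.null(names(x)) || any(names(x) == ""))
        stop("basis function lists must be named")
      fns <- x
    } else stop("basis must be a character vector or a named list of functions")
    if (!allow_const && "const" %in% names(fns))
      stop("alpha_basis may not contain the constant (absorbed by the baseline)")
    fns
  }
  beta <- pick(beta_basis, allow_const = TRUE)
  if (!any(vapply(beta, function(f) isTRUE(all.equal(unname(f(c(0, 2.5))), c(1, 1))),
                  logical(1L))))
    stop("beta_basis must contain the constant function (the main effect)")
  alpha <- if (length(alpha_basis)) pick(alpha_basis, allow_const = FALSE) else list()
  structure(list(beta = beta, alpha = alpha), class = "lm_td_spec")
}

#' Build the stacked landmark dataset
#'
#' For every landmark s in the grid and every subject still event-free at s
#' (outcome time strictly greater than s), emits one counting-process row
#' with `entry = s`, `exit = min(T, s + w)`, `status` equal to the subject's
#' cause code if the event falls inside the window and 0 otherwise
#' (administrative censoring at s + w), and covariates carried forward to s.
#' Rows from all landmarks are concatenated into one extended dataset on
#' which the supermodel is fitted.
#'
#' @param cohort an `lm_cohort`.
#' @param grid an `lm_grid`.
#' @return data frame of class `lm_stack` with reserved columns
#'   `id, LM, entry, exit, status` followed by the covariates; the grid,
#'   covariate names and number of causes are kept as attributes.
#' @export
build_stack <- function(cohort, grid) {
  stopifnot(inherits(cohort, "lm_cohort"), inherits(grid, "lm_grid"))
  out <- cohort$outcomes
  if (nrow(out) == 0L) stop("cohort is empty")
  w <- grid$window
  pieces <- vector("list", length(grid$landmarks))
  for (li in seq_along(grid$landmarks)) {
    s <- grid$landmarks[li]
    at_risk <- out$time > s
    if (!any(at_risk)) {
      warning("empty risk set at landmark s = ", s, call. = FALSE)
      next
    }
    ids <- out$id[at_risk]
    ti <- out$time[at_risk]
    in_window <- ti <= s + w
    Z <- locf_covariates(cohort, s, ids = ids)
    pieces[[li]] <- data.frame(
      id = ids, LM = s, entry = s,
      exit = pmin(ti, s + w),
      status = ifelse(in_window, out$status[at_risk], 0L),
      Z[cohort$covariates],
      check.names = FALSE)
  }
  stk <- do.call(rbind, pieces)
  if (is.null(stk))
    stk <- data.frame(id = character(), LM = numeric(), entry = numeric(),
                      exit = numeric(), status = integer())
  rownames(stk) <- NULL
  structure(stk, class = c("lm_stack", "data.frame"),
            grid = grid, covariates = cohort$covariates,
            n_causes = cohort$n_causes)
}

#' Expand a stacked dataset into the supermodel design matrix
#'
#' Builds the time-interaction design: one column f_m(s) * Z_k per
#' beta-basis function and covariate, followed by the alpha columns
#' g_q(s - s0).  The returned column map records the source covariate and
#' basis of every column so fitted coefficients can be reported as main
#' vs time-dependent effects.
#'
#' @param stack an `lm_stack` (or any data frame with an `LM` column and the
#'   covariates named in `covariates`).
#' @param spec an `lm_td_spec`.
#' @param covariates covariate columns to use; defaults to the stack's.
#' @param s0 first landmark, used to anchor the alpha basis; defaults to the
#'   grid stored on the stack.
#' @return list with `X` (numeric matrix, one row per stacked row) and
#'   `map` (data frame: `column`, `covariate` (NA for alpha columns),
#'   `basis`, `type` in main/td/alpha).
#' @export
expand_design <- function(stack, spec, covariates = NULL, s0 = NULL) {
  stopifnot(inherits(spec, "lm_td_spec"))
  if (nrow(stack) == 0L) stop("stack is empty")
  if (is.null(covariates)) covariates <- attr(stack, "covariates")
  if (is.null(covariates)) stop("covariates not given and not found on the stack")
  if (is.null(s0)) {
    g <- attr(stack, "grid")
    s0 <- if (!is.null(g)) g$landmarks[1L] else min(stack$LM)
  }
  s <- stack$LM
  nb <- length(spec$beta); na <- length(spec$alpha)
  p <- length(covariates)
  X <- matrix(0.0, nrow(stack), p * nb + na)
  cn <- character(ncol(X)); map_cov <- character(ncol(X))
  map_basis <- character(ncol(X)); map_type <- character(ncol(X))
  col <- 0L
  for (k in seq_len(p)) {
    z <- as.numeric(stack[[covariates[k]]])
    if (anyNA(z)) stop("missing values in covariate ", covariates[k])
    for (m in seq_len(nb)) {
      fs <- spec$beta[[m]](s)
      if (any(!is.finite(fs)))
        stop("non-finite beta-basis value for basis '", names(spec$beta)[m],
             "' at landmark s = ", s[which(!is.finite(fs))[1L]])
      col <- col + 1L
      X[, col] <- fs * z
      bnm <- names(spec$beta)[m]
      cn[col] <- if (bnm == "const") covariates[k] else paste0(covariates[k], ":", bnm)
      map_cov[col] <- covariates[k]; map_basis[col] <- bnm
      map_type[col] <- if (bnm == "const") "main" else "td"
    }
  }
  for (q in seq_len(na)) {
    gs <- spec$alpha[[q]](s - s0)
    if (any(!is.finite(gs)))
      stop("non-finite alpha-basis value for basis '", names(spec$alpha)[q],
           "' at landmark s = ", s[which(!is.finite(gs))[1L]])
    col <- col + 1L
    X[, col] <- gs
    cn[col] <- paste0("LM:", names(spec$alpha)[q])
    map_cov[col] <- NA_character_; map_basis[col] <- names(spec$alpha)[q]
    map_type[col] <- "alpha"
  }
  colnames(X) <- cn
  list(X = X,
       map = data.frame(column = cn, covariate = map_cov,
                        basis = map_basis, type = map_type))
}

#' Write a stacked landmark dataset to CSV
#' @param stack an `lm_stack`.
#' @param file destination path.
#' @return Invisibly, the stack.
#' @export
write_stack <- function(stack, file) {
  utils::write.csv(as.data.frame(stack), file, row.names = FALSE)
  invisible(stack)
}
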