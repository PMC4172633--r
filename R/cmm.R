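#' Control settings for contest mixed-model fits
#'
#' @param grad_tol Gradient-norm tolerance used to declare convergence of the
#'   outer optimisation over variance parameters (and, for the binomial
#'   family, fixed effects).
#' @param max_iter Maximum outer iterations.
#' @param inner_tol Convergence tolerance of the inner Newton iteration that
#'   locates the conditional mode of the random effects (binomial family).
#' @param inner_max_iter Maximum inner Newton iterations.
#' @param start_grid Fixed multi-start grid for the variance components: each
#'   value is used, in turn, as the common starting value of every variance
#'   ratio (Gaussian) or random-effect standard deviation (binomial).  The
#'   grid is fixed so that fits are deterministic.
#' @param log_var_bounds Bounds for the log variance-ratio parameters; the
#'   lower bound acts as the zero-variance boundary.
#' @return A list of control settings for [cmm()].
#' @export
cmm_control <- function(grad_tol = 1e-6, max_iter = 500,
                        inner_tol = 1e-10, inner_max_iter = 60,
                        start_grid = c(0.1, 1, 4),
                        log_var_bounds = c(-18, 12)) {
  stopifnot(grad_tol > 0, max_iter >= 1, length(start_grid) >= 1,
            length(log_var_bounds) == 2, diff(log_var_bounds) > 0)
  list(grad_tol = grad_tol, max_iter = max_iter, inner_tol = inner_tol,
       inner_max_iter = inner_max_iter, start_grid = start_grid,
       log_var_bounds = log_var_bounds)
}

# ---------------------------------------------------------------------------
# formula handling: response ~ fixed terms + (1 | g1) + (1 | g2)
# only random intercepts are supported; that is the whole model class here.

parse_mixed_formula <- function(formula) {
  if (length(formula) != 3L)
    stop("formula must have a response, e.g. y ~ x + (1 | g)")
  bars <- list()
  fixed <- list()
  walk <- function(e) {
    if (is.call(e) && identical(e[[1L]], as.name("+"))) {
      walk(e[[2L]]); walk(e[[3L]])
    } else if (is.call(e) && identical(e[[1L]], as.name("("))) {
      walk(e[[2L]])
    } else if (is.call(e) && identical(e[[1L]], as.name("|"))) {
      bars[[length(bars) + 1L]] <<- e
    } else {
      fixed[[length(fixed) + 1L]] <<- e
    }
  }
  walk(formula[[3L]])
  groups <- character(0)
  for (b in bars) {
    if (!identical(b[[2L]], 1) && !identical(b[[2L]], 1L))
      stop("only random intercepts '(1 | group)' are supported")
    if (!is.name(b[[3L]]))
      stop("random-effect grouping must be a single column name")
    groups <- c(groups, as.character(b[[3L]]))
  }
  if (anyDuplicated(groups))
    stop("duplicated random-intercept grouping factor: ",
         groups[duplicated(groups)][1L])
  fixed_terms <- vapply(fixed, function(e) paste(deparse(e), collapse = ""),
                        character(1))
  fixed_terms <- fixed_terms[fixed_terms != "1"]
  fixed_rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(
    paste(deparse(formula[[2L]]), "~", fixed_rhs), env = environment(formula))
  list(fixed = fixed_formula, groups = groups)
}

# ---------------------------------------------------------------------------
# Gaussian family: profiled (RE)ML over variance ratios gamma_k = s2_k / s2_e.
# All n-dimensional quantities are reduced once to crossproducts, so each
# objective evaluation works in the random-effect dimension q via the
# Woodbury identity: V0^-1 = I - Z (G^-1 + Z'Z)^-1 Z' with G = diag(gamma).

gaussian_profile_dev <- function(loggamma, pre, REML) {
  n <- pre$n; p <- pre$p
  gvec <- exp(loggamma)[pre$block]
  A <- pre$ZtZ
  diag(A) <- diag(A) + 1 / gvec
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(list(dev = 1e10))
  logdetV0 <- 2 * sum(log(diag(chA))) + sum(log(gvec))
  Ai_ZtX <- chol_solve(chA, pre$ZtX)
  Ai_Zty <- chol_solve(chA, pre$Zty)
  M <- pre$XtX - crossprod(pre$ZtX, Ai_ZtX)         # X' V0^-1 X
  XtVy <- pre$Xty - crossprod(pre$ZtX, Ai_Zty)      # X' V0^-1 y
  yVy <- pre$yty - drop(crossprod(pre$Zty, Ai_Zty)) # y' V0^-1 y
  chM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(chM)) return(list(dev = 1e10))
  beta <- chol_solve(chM, XtVy)
  quad <- yVy - 2 * drop(crossprod(beta, XtVy)) +
    drop(crossprod(beta, M %*% beta))
  if (quad <= 0) return(list(dev = 1e10))
  if (REML) {
    s2 <- quad / (n - p)
    dev <- (n - p) * log(2 * pi * s2) + logdetV0 +
      2 * sum(log(diag(chM))) + (n - p)
  } else {
    s2 <- quad / n
    dev <- n * log(2 * pi * s2) + logdetV0 + n
  }
  # Z' V0^-1 r, needed for the BLUPs: Z'r - Z'Z A^-1 Z'r
  Ztr <- pre$Zty - pre$ZtX %*% beta
  ZVr <- drop(Ztr - pre$ZtZ %*% chol_solve(chA, Ztr))
  list(dev = dev, beta = drop(beta), s2 = s2,
       vcov = s2 * chol2inv(chM), ZVr = ZVr)
}

fit_cmm_gaussian <- function(y, X, Zlist, REML, control) {
  n <- length(y); p <- ncol(X); K <- length(Zlist)
  if (qr(X)$rank < p) {
    stop("singular fixed-effect design: columns {",
         paste(colnames(X), collapse = ", "), "} are collinear")
  }
  if (K == 0L) {
    fit <- stats::lm.fit(X, y)
    r <- fit$residuals
    rss <- sum(r^2)
    s2 <- rss / if (REML) (n - p) else n
    XtXi <- chol2inv(chol(crossprod(X)))
    ll <- if (REML) {
      -0.5 * ((n - p) * log(2 * pi * s2) +
                2 * sum(log(diag(chol(crossprod(X))))) + (n - p))
    } else {
      -0.5 * (n * log(2 * pi * s2) + n)
    }
    return(list(beta = stats::coef(fit), vcov = s2 * XtXi, s2 = s2,
                varcomp = numeric(0), loglik = ll, converged = TRUE,
                boundary = logical(0), u = list()))
  }
  Z <- do.call(cbind, Zlist)
  qk <- vapply(Zlist, ncol, integer(1))
  block <- rep(seq_len(K), qk)
  pre <- list(n = n, p = p, block = block,
              ZtZ = crossprod(Z), ZtX = crossprod(Z, X),
              Zty = drop(crossprod(Z, y)), XtX = crossprod(X),
              Xty = drop(crossprod(X, y)), yty = sum(y^2))
  obj <- function(lg) gaussian_profile_dev(lg, pre, REML)$dev
  lo <- control$log_var_bounds[1]; hi <- control$log_var_bounds[2]
  best <- NULL
  for (g0 in control$start_grid) {
    op <- stats::optim(rep(log(g0), K), obj, method = "L-BFGS-B",
                       lower = lo, upper = hi,
                       control = list(maxit = control$max_iter,
                                      factr = 1e4))
    if (is.null(best) || op$value < best$value) best <- op
  }
  lg <- best$par
  at_lo <- lg <= lo + 1e-3
  fit <- gaussian_profile_dev(lg, pre, REML)
  gamma <- exp(lg)
  gamma[at_lo] <- 0
  varcomp <- gamma * fit$s2
  names(varcomp) <- names(Zlist)
  # BLUPs of random intercepts: u_k = gamma_k Z_k' V0^-1 r
  u <- split(gamma[block] * fit$ZVr, block)
  u <- lapply(seq_len(K), function(k) {
    uk <- u[[k]]; names(uk) <- colnames(Zlist[[k]]); uk
  })
  names(u) <- names(Zlist)
  gn <- num_grad(obj, lg)
  # L-BFGS-B can end with an abnormal line-search code in the flat region
  # near a zero-variance boundary; a vanished gradient is still an optimum
  converged <- best$convergence == 0 || max(abs(gn)) < 1e-3
  list(beta = fit$beta, vcov = fit$vcov, s2 = fit$s2, varcomp = varcomp,
       loglik = -fit$dev / 2, converged = converged, boundary = at_lo,
       u = u, grad_norm = max(abs(gn)))
}

# ---------------------------------------------------------------------------
# Binomial family: Laplace-approximate marginal likelihood.
# Outer optimisation over (beta, log sigma_k); inner Newton iteration with
# step halving finds the conditional mode of the stacked random effects.
# Because Z is a column-bound pair of indicator matrices, every Z product is
# an aggregation by group index, never a dense matrix product.

# Precompute the aggregation layout of the indicator factors.  Group sums
# are dense products with the indicator matrices (rowsum would re-sort its
# keys on every call); the integer indices serve only to build the linear
# predictor.
laplace_layout <- function(idx, qk, Zlist) {
  list(idx = idx, qk = qk, K = length(idx), off = cumsum(c(0L, qk)),
       Z1 = Zlist[[1L]], Z2 = if (length(Zlist) > 1L) Zlist[[2L]])
}

# Newton step, log-determinant and solve for H = Z'WZ + D^-1, exploiting the
# block structure [[diag(d1), B], [B', diag(d2)]] of crossed intercepts via
# the Schur complement S = diag(d2) - B' diag(1/d1) B.
laplace_factor <- function(w, lay, dinv) {
  d1 <- drop(crossprod(lay$Z1, w)) + dinv[lay$off[1L] + seq_len(lay$qk[1L])]
  if (any(d1 <= 0)) return(NULL)
  if (lay$K == 1L) {
    return(list(d1 = d1, logdet = sum(log(d1))))
  }
  d2 <- drop(crossprod(lay$Z2, w)) + dinv[lay$off[2L] + seq_len(lay$qk[2L])]
  B <- crossprod(lay$Z1, lay$Z2 * w)
  S <- -crossprod(B / d1, B)
  diag(S) <- diag(S) + d2
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) return(NULL)
  list(d1 = d1, B = B, chS = chS,
       logdet = sum(log(d1)) + 2 * sum(log(diag(chS))))
}

laplace_solve <- function(fac, g, lay) {
  if (lay$K == 1L) return(g / fac$d1)
  g1 <- g[seq_len(lay$qk[1L])]
  g2 <- g[lay$off[2L] + seq_len(lay$qk[2L])]
  s2 <- drop(chol_solve(fac$chS, g2 - drop(crossprod(fac$B, g1 / fac$d1))))
  s1 <- (g1 - drop(fac$B %*% s2)) / fac$d1
  c(s1, s2)
}

binomial_laplace_negll <- function(psi, y, X, lay, block, p, K, control,
                                   u_env = NULL) {
  beta <- psi[seq_len(p)]
  Xb <- drop(X %*% beta)
  if (K == 0L) {
    eta <- Xb
    return(-(sum(y * eta - log1pexp(eta))))
  }
  sig2 <- exp(2 * psi[p + seq_len(K)])
  dinv <- 1 / sig2[block]
  qk <- lay$qk; off <- lay$off; idx <- lay$idx
  q <- sum(qk)
  re_part <- function(u) {
    eta <- Xb
    for (k in seq_len(K)) eta <- eta + u[off[k] + idx[[k]]]
    eta
  }
  u <- if (!is.null(u_env) && length(u_env$u) == q) u_env$u else numeric(q)
  pen_ll <- function(u) {
    eta <- re_part(u)
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(dinv * u^2)
  }
  h_cur <- pen_ll(u)
  for (it in seq_len(control$inner_max_iter)) {
    eta <- re_part(u)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    resid <- y - mu
    g <- if (K == 1L) drop(crossprod(lay$Z1, resid))
    else c(drop(crossprod(lay$Z1, resid)), drop(crossprod(lay$Z2, resid)))
    g <- g - dinv * u
    fac <- laplace_factor(w, lay, dinv)
    if (is.null(fac)) return(1e10)
    step <- laplace_solve(fac, g, lay)
    # step halving keeps the penalised log-likelihood monotone
    alpha <- 1
    repeat {
      u_new <- u + alpha * step
      h_new <- pen_ll(u_new)
      if (h_new >= h_cur - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    moved <- h_new - h_cur
    u <- u_new; h_cur <- h_new
    if (max(abs(g)) < 1e-7 || abs(moved) < control$inner_tol) break
  }
  eta <- re_part(u)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  fac <- laplace_factor(w, lay, dinv)
  if (is.null(fac)) return(1e10)
  if (!is.null(u_env)) u_env$u <- u
  ll <- h_cur - 0.5 * sum(log(sig2[block])) - 0.5 * fac$logdet
  -ll
}

fit_cmm_binomial <- function(y, X, Zlist, control) {
  n <- length(y); p <- ncol(X); K <- length(Zlist)
  if (!all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1")
  if (n < p + 2L)
    stop("too few observations (", n, ") for ", p, " fixed-effect parameters")
  if (qr(X)$rank < p)
    stop("singular fixed-effect design: columns {",
         paste(colnames(X), collapse = ", "), "} are collinear")
  glm0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta0 <- glm0$coefficients
  beta0[!is.finite(beta0)] <- 0
  if (K == 0L) {
    eta <- drop(X %*% beta0)
    ll <- sum(y * eta - log1pexp(eta))
    W <- glm0$weights
    vc <- tryCatch(chol2inv(chol(crossprod(X, X * W))),
                   error = function(e) matrix(NA_real_, p, p))
    sep <- max(abs(beta0)) > 15 || max(abs(eta)) > 30
    return(list(beta = beta0, vcov = vc, varcomp = numeric(0), loglik = ll,
                converged = glm0$converged, boundary = logical(0),
                separation = sep, u = list()))
  }
  qk <- vapply(Zlist, ncol, integer(1))
  block <- rep(seq_len(K), qk)
  idx <- lapply(Zlist, function(Zk) max.col(Zk, ties.method = "first"))
  lay <- laplace_layout(idx, qk, Zlist)
  u_env <- new.env(parent = emptyenv())
  f <- function(psi) binomial_laplace_negll(psi, y, X, lay, block, p, K,
                                            control, u_env)
  lo <- c(rep(-Inf, p), rep(control$log_var_bounds[1] / 2, K))
  hi <- c(rep(Inf, p), rep(control$log_var_bounds[2] / 2, K))
  best <- NULL
  for (s0 in control$start_grid) {
    u_env$u <- numeric(sum(qk))
    op <- stats::nlminb(c(beta0, rep(log(sqrt(s0)), K)), f,
                        lower = lo, upper = hi,
                        control = list(iter.max = control$max_iter,
                                       rel.tol = 1e-10))
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  psi <- best$par
  # evaluate once more at the optimum so u_env holds the matching mode
  f(psi)
  beta <- psi[seq_len(p)]
  names(beta) <- colnames(X)
  logsig <- psi[p + seq_len(K)]
  at_lo <- logsig <= control$log_var_bounds[1] / 2 + 1e-3
  varcomp <- exp(2 * logsig)
  varcomp[at_lo] <- 0
  names(varcomp) <- names(Zlist)
  Hp <- num_hess(f, psi)
  vc <- tryCatch(solve(Hp)[seq_len(p), seq_len(p), drop = FALSE],
                 error = function(e) {
                   # fall back to the beta block with variances held fixed
                   Hb <- Hp[seq_len(p), seq_len(p), drop = FALSE]
                   tryCatch(solve(Hb), error = function(e2)
                     matrix(NA_real_, p, p))
                 })
  off <- cumsum(c(0L, qk))
  eta <- drop(X %*% beta)
  for (k in seq_len(K)) eta <- eta + u_env$u[off[k] + idx[[k]]]
  sep <- max(abs(beta)) > 15 || max(abs(eta)) > 30
  gn <- num_grad(f, psi)
  converged <- best$convergence == 0 || max(abs(gn)) < 1e-3
  u <- split(u_env$u, block)
  u <- lapply(seq_len(K), function(k) {
    uk <- u[[k]]; names(uk) <- colnames(Zlist[[k]]); uk
  })
  names(u) <- names(Zlist)
  list(beta = beta, vcov = vc, varcomp = varcomp, loglik = -best$objective,
       converged = converged, boundary = at_lo,
       separation = sep, u = u, grad_norm = max(abs(gn)))
}

# ---------------------------------------------------------------------------

#' Fit a contest mixed model with crossed random intercepts
#'
#' Fits the two model families used in the two-step contest analysis:
#' a mixed-effects logistic regression of a binary contest outcome
#' (Laplace-approximate maximum likelihood) and a Gaussian linear mixed
#' model of log-transformed contest duration (REML by default).  Random
#' effects are restricted to crossed random intercepts, typically one for
#' each contestant identity, written in the familiar `(1 | group)` notation.
#'
#' For the binomial family the marginal likelihood integrates the random
#' intercepts out with a Laplace approximation around their conditional
#' mode, located by a penalised Newton iteration with step halving; the
#' outer optimisation runs over the fixed effects and the log random-effect
#' standard deviations from a fixed multi-start grid, so fits are fully
#' deterministic.  For the Gaussian family the fixed effects and residual
#' variance are profiled out analytically and the optimisation runs over the
#' log variance ratios; variance components estimated on the zero boundary
#' are reported as exactly zero with `boundary` flagged.
#'
#' @param formula Model formula such as
#'   `outcome ~ rpd_cinc + (1 | focal_state) + (1 | opponent_state)`.
#'   Only random intercepts are supported; at most two fixed predictors.
#' @param data Data frame containing every variable in the formula.
#' @param family `"gaussian"` or `"binomial"`.
#' @param REML For the Gaussian family, use restricted maximum likelihood
#'   (default).  Ignored for the binomial family, which is always fitted by
#'   (Laplace-approximate) maximum likelihood.
#' @param control A list from [cmm_control()].
#' @return An object of class `"cmm"` with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `residuals`, `ranef` and `simulate`
#'   methods.
#' @seealso [lr_test()] for likelihood-ratio comparison of nested fits,
#'   [f_test()] for F tests of single fixed effects with Satterthwaite
#'   denominator degrees of freedom.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = factor(rep(1:8, each = 5)), x = rnorm(40))
#' d$y <- 1 + 0.8 * d$x + rnorm(8, sd = 0.7)[d$g] + rnorm(40, sd = 0.4)
#' fit <- cmm(y ~ x + (1 | g), d)
#' summary(fit)
#' @export
cmm <- function(formula, data, family = c("gaussian", "binomial"),
                REML = TRUE, control = cmm_control()) {
  family <- match.arg(family)
  parts <- parse_mixed_formula(formula)
  mf <- stats::model.frame(parts$fixed, data = data, na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  keep <- attr(mf, "na.action")
  used <- if (is.null(keep)) seq_len(nrow(data)) else setdiff(seq_len(nrow(data)), keep)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(parts$fixed, mf)
  if (ncol(X) > 3L)
    stop("at most two fixed predictors are supported in this model class")
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
    stop("response must be numeric and finite")
  Zlist <- list()
  for (g in parts$groups) {
    if (is.null(data[[g]]))
      stop("grouping column '", g, "' not found in data")
    fac <- factor(data[[g]][used])
    Zk <- stats::model.matrix(~ 0 + fac)
    colnames(Zk) <- levels(fac)
    Zlist[[g]] <- Zk
  }
  if (length(Zlist) > 2L)
    stop("at most two crossed random-intercept factors are supported")
  fit <- if (family == "gaussian") {
    fit_cmm_gaussian(y, X, Zlist, REML = REML, control = control)
  } else {
    fit_cmm_binomial(y, X, Zlist, control = control)
  }
  beta <- fit$beta
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(as.matrix(fit$vcov)), 0))
  names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, vcov = fit$vcov,
    varcomp = fit$varcomp,
    sigma2 = if (family == "gaussian") fit$s2 else NULL,
    loglik = fit$loglik,
    REML = if (family == "gaussian") REML else FALSE,
    family = family, converged = fit$converged,
    boundary = fit$boundary,
    separation = fit$separation %||% FALSE,
    grad_norm = fit$grad_norm %||% NA_real_,
    u = fit$u,
    n = length(y), p = ncol(X),
    n_groups = vapply(Zlist, ncol, integer(1)),
    formula = formula, fixed_formula = parts$fixed, groups = parts$groups,
    y = y, X = X, Zlist = Zlist,
    control = control, call = match.call()
  ), class = "cmm")
}

# refit a gaussian REML model by ML (needed for likelihood-ratio tests)
refit_ml <- function(object) {
  if (object$family != "gaussian" || !object$REML) return(object)
  fit <- fit_cmm_gaussian(object$y, object$X, object$Zlist, REML = FALSE,
                          control = object$control)
  object$coefficients <- structure(fit$beta, names = colnames(object$X))
  object$vcov <- fit$vcov
  object$se <- sqrt(pmax(diag(as.matrix(fit$vcov)), 0))
  object$varcomp <- fit$varcomp
  object$sigma2 <- fit$s2
  object$loglik <- fit$loglik
  object$converged <- fit$converged
  object$boundary <- fit$boundary
  object$u <- fit$u
  object$REML <- FALSE
  object
}
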