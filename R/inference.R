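#' @export
print.cmm_test <- function(x, ...) {
  if (is.na(x$df2)) {
    cat(sprintf("%s: chisq(%g) = %.4g, p = %.4g\n",
                x$method, x$df1, x$statistic, x$p_value))
  } else {
    cat(sprintf("%s: F(%g, %.4g) = %.4g, p = %.4g\n",
                x$method, x$df1, x$df2, x$statistic, x$p_value))
  }
  invisible(x)
}

new_cmm_test <- function(method, statistic, df1, df2, p_value, note = NULL) {
  structure(list(method = method, statistic = statistic, df1 = df1,
                 df2 = df2, p_value = p_value, note = note),
            class = "cmm_test")
}

fixed_term_labels <- function(object) {
  attr(stats::terms(object$fixed_formula), "term.labels")
}

# refit with a wider, still fixed, multi-start grid
refit_restarts <- function(object) {
  control <- object$control
  control$start_grid <- c(0.02, 0.1, 0.5, 1, 4, 16)
  fit <- if (object$family == "gaussian") {
    fit_cmm_gaussian(object$y, object$X, object$Zlist, REML = object$REML,
                     control = control)
  } else {
    fit_cmm_binomial(object$y, object$X, object$Zlist, control = control)
  }
  if (fit$loglik > object$loglik) {
    object$coefficients <- structure(fit$beta, names = colnames(object$X))
    object$vcov <- fit$vcov
    object$se <- sqrt(pmax(diag(as.matrix(fit$vcov)), 0))
    object$varcomp <- fit$varcomp
    if (object$family == "gaussian") object$sigma2 <- fit$s2
    object$loglik <- fit$loglik
    object$converged <- fit$converged
    object$boundary <- fit$boundary
    object$u <- fit$u
  }
  object
}

#' Likelihood-ratio test between nested contest mixed models
#'
#' Compares two nested fits of the same family on the same data by the
#' likelihood-ratio chi-square.  Gaussian models fitted by REML are
#' automatically refitted by maximum likelihood, since restricted
#' likelihoods of models with different fixed effects are not comparable.
#' The statistic is clamped at zero; if the reduced model appears to beat
#' the full model by more than numerical tolerance, the full model is
#' refitted from a wider multi-start grid before the comparison is declared
#' inconsistent.
#'
#' @param full,reduced Fitted [cmm()] models; `reduced`'s fixed effects must
#'   be a subset of `full`'s, with identical response, family and random
#'   structure.
#' @return A `"cmm_test"` object with the chi-square statistic, numerator
#'   degrees of freedom and p-value.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "cmm"), inherits(reduced, "cmm"))
  if (full$family != reduced$family)
    stop("models have different families; not nested")
  if (!setequal(full$groups, reduced$groups))
    stop("models have different random structures; not nested")
  if (full$n != reduced$n)
    stop("models were fitted to different numbers of observations (",
         full$n, " vs ", reduced$n, ")")
  tf <- fixed_term_labels(full); tr <- fixed_term_labels(reduced)
  if (!all(tr %in% tf))
    stop("reduced model's fixed effects are not a subset of the full model's")
  if (length(tr) == length(tf))
    warning("models have identical fixed effects; statistic is 0 by construction")
  full <- refit_ml(full); reduced <- refit_ml(reduced)
  if (reduced$loglik > full$loglik + 1e-6) {
    full <- refit_restarts(full)
    if (reduced$loglik > full$loglik + 1e-6)
      stop("reduced model has higher likelihood than the full model even ",
           "after restarts; fits are unreliable")
  }
  df1 <- full$p - reduced$p
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df1 == 0) 1 else stats::pchisq(stat, df1, lower.tail = FALSE)
  new_cmm_test("LR-chisq", stat, df1, NA_real_, p)
}

# ---------------------------------------------------------------------------
# Satterthwaite denominator degrees of freedom.
#
# The REML log-likelihood is treated as a function of the raw variance
# parameters phi = (residual variance, each non-boundary random-intercept
# variance).  The contrast variance g(phi) = c' (X' V^-1 X)^-1 c is
# differentiated numerically and combined with the asymptotic covariance of
# phi-hat (inverse observed REML information) in the usual
# df = 2 g^2 / (grad' Cov grad) formula.

reml_negll_phi <- function(phi, y, X, ZZt) {
  n <- length(y); p <- ncol(X)
  if (any(phi <= 0)) return(1e10)
  V <- diag(phi[1], n)
  for (k in seq_along(ZZt)) V <- V + phi[k + 1] * ZZt[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi_X <- chol_solve(ch, X)
  M <- crossprod(X, Vi_X)
  chM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(chM)) return(1e10)
  beta <- chol_solve(chM, crossprod(Vi_X, y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, chol_solve(ch, r)))
  0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chM))) + quad +
           (n - p) * log(2 * pi))
}

contrast_var_phi <- function(phi, X, ZZt, cvec) {
  n <- nrow(X)
  V <- diag(phi[1], n)
  for (k in seq_along(ZZt)) V <- V + phi[k + 1] * ZZt[[k]]
  ch <- chol(V)
  M <- crossprod(X, chol_solve(ch, X))
  drop(crossprod(cvec, solve(M, cvec)))
}

satterthwaite_df <- function(object, cvec) {
  active <- which(object$varcomp > 0)
  if (object$family != "gaussian")
    stop("Satterthwaite degrees of freedom require a Gaussian fit")
  if (length(active) == 0L) return(object$n - object$p)
  ZZt <- lapply(object$Zlist[active], tcrossprod)
  phi <- c(object$sigma2, unname(object$varcomp[active]))
  y <- object$y; X <- object$X
  g0 <- contrast_var_phi(phi, X, ZZt, cvec)
  grad <- num_grad(function(ph) contrast_var_phi(ph, X, ZZt, cvec), phi,
                   h = 1e-4)
  H <- num_hess(function(ph) reml_negll_phi(ph, y, X, ZZt), phi, h = 1e-3)
  cov_phi <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_phi)) return(NA_real_)
  denom <- drop(crossprod(grad, cov_phi %*% grad))
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  df <- 2 * g0^2 / denom
  # never report more information than the residual df
  min(df, object$n - object$p)
}

#' F test of a single fixed effect in a Gaussian contest mixed model
#'
#' Tests one fixed-effect coefficient with an F statistic whose denominator
#' degrees of freedom account for the estimated random-effect structure.
#' The Satterthwaite approximation is the implemented method; requesting
#' Kenward-Roger falls through to Satterthwaite with a note, and the method
#' actually used is always recorded in the result.  With every variance
#' component on the zero boundary the test reduces exactly to the classical
#' linear-regression F with `n - p` denominator degrees of freedom.
#'
#' @param model A Gaussian [cmm()] fit (REML recommended).
#' @param predictor Name of the fixed-effect column to test.
#' @param df_method `"satterthwaite"` (implemented) or `"KR"` (falls back to
#'   Satterthwaite, with the fallback noted in the result).
#' @return A `"cmm_test"` object with the F statistic, numerator and
#'   (generally fractional) denominator degrees of freedom, and p-value.
#' @export
f_test <- function(model, predictor,
                   df_method = c("satterthwaite", "KR")) {
  stopifnot(inherits(model, "cmm"))
  df_method <- match.arg(df_method)
  if (model$family != "gaussian")
    stop("F tests are defined here for the Gaussian family only")
  j <- match(predictor, names(model$coefficients))
  if (is.na(j))
    stop("'", predictor, "' is not a fixed effect of the model")
  note <- NULL
  if (df_method == "KR") {
    note <- "Kenward-Roger requested; Satterthwaite approximation used"
    message(note)
  }
  cvec <- rep(0, model$p); cvec[j] <- 1
  df2 <- satterthwaite_df(model, cvec)
  Fstat <- (model$coefficients[[j]] / model$se[[j]])^2
  p <- if (is.na(df2)) NA_real_ else stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  new_cmm_test("F-Satterthwaite", Fstat, 1, df2, p, note = note)
}

#' Pairwise collinearity screen for candidate predictors
#'
#' Computes the pairwise Pearson correlation matrix of a set of predictor
#' columns and flags every pair whose absolute correlation exceeds a
#' threshold.  In the contest pipeline this motivates fitting one power
#' predictor per duration model rather than a joint multiple regression:
#' winner, loser and relative power of the same measure are typically far
#' too correlated to separate.
#'
#' @param data Data frame.
#' @param columns At least two numeric column names.
#' @param threshold Absolute-correlation flag level (default 0.7).
#' @return A `"collinearity_report"`: the correlation matrix, a data frame of
#'   flagged pairs, and a data frame of pairs whose correlation is undefined
#'   (constant columns).
#' @export
collinearity_report <- function(data, columns, threshold = 0.7) {
  stopifnot(length(columns) >= 2, nrow(data) >= 3)
  miss <- setdiff(columns, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  m <- as.matrix(data[columns])
  storage.mode(m) <- "double"
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  flagged <- data.frame(col_a = character(0), col_b = character(0),
                        r = numeric(0))
  undefined <- flagged[c("col_a", "col_b")]
  for (i in seq_len(length(columns) - 1)) for (j in seq((i + 1), length(columns))) {
    r <- cm[i, j]
    if (is.na(r)) {
      undefined <- rbind(undefined,
                         data.frame(col_a = columns[i], col_b = columns[j]))
    } else if (abs(r) > threshold) {
      flagged <- rbind(flagged,
                       data.frame(col_a = columns[i], col_b = columns[j], r = r))
    }
  }
  structure(list(correlations = cm, flagged = flagged, undefined = undefined,
                 threshold = threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Pairwise correlations (flag threshold |r| >", x$threshold, "):\n")
  print(round(x$correlations, 3))
  if (nrow(x$flagged)) {
    cat("Flagged pairs:\n"); print(x$flagged)
  } else cat("No pairs flagged.\n")
  if (nrow(x$undefined)) {
    cat("Undefined (constant column) pairs:\n"); print(x$undefined)
  }
  invisible(x)
}
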