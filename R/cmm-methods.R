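#' @export
print.cmm <- function(x, ...) {
  cat("Contest mixed model (", x$family,
      if (x$family == "gaussian") if (x$REML) ", REML" else ", ML"
      else ", Laplace ML", ")\n", sep = "")
  cat("Formula:", deparse(x$formula), "\n")
  cat("Observations:", x$n, "\n")
  if (length(x$n_groups)) {
    cat("Groups:", paste(sprintf("%s (%d)", names(x$n_groups), x$n_groups),
                         collapse = ", "), "\n")
  }
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  if (length(x$varcomp)) {
    cat("Random-intercept variances:\n")
    print(round(x$varcomp, 4))
  }
  if (!is.null(x$sigma2)) cat("Residual variance:", round(x$sigma2, 4), "\n")
  cat("Log-likelihood:", round(x$loglik, 3), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (isTRUE(x$separation)) cat("WARNING: possible complete separation\n")
  invisible(x)
}

#' @export
summary.cmm <- function(object, ...) {
  z <- object$coefficients / object$se
  coefs <- cbind(Estimate = object$coefficients,
                 `Std. Error` = object$se,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(object = object, coefficients = coefs), class = "summary.cmm")
}

#' @export
print.summary.cmm <- function(x, ...) {
  print(x$object)
  cat("\nCoefficient table (Wald z, asymptotic):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.cmm <- function(object, ...) object$coefficients

#' @export
vcov.cmm <- function(object, ...) {
  v <- as.matrix(object$vcov)
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
logLik.cmm <- function(object, ...) {
  df <- object$p + length(object$varcomp) +
    if (object$family == "gaussian") 1L else 0L
  structure(object$loglik, df = df, nobs = object$n,
            class = "logLik")
}

#' Random-intercept modes of a contest mixed model
#'
#' Returns the conditional modes (Gaussian family: BLUPs) of the random
#' intercepts, one named vector per grouping factor.
#' @param object A fitted [cmm()] model.
#' @param ... Unused.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.cmm <- function(object, ...) object$u

# linear predictor on the link scale; random effects included unless
# re_form = NA
cmm_linpred <- function(object, newdata = NULL, re_form = NULL) {
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
    if (!identical(re_form, NA)) {
      for (g in names(object$Zlist))
        eta <- eta + drop(object$Zlist[[g]] %*% object$u[[g]])
    }
    return(eta)
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$fixed_formula)),
                           newdata)
  eta <- drop(X %*% object$coefficients)
  if (!identical(re_form, NA)) {
    for (g in object$groups) {
      lev <- as.character(newdata[[g]])
      uk <- object$u[[g]]
      add <- ifelse(lev %in% names(uk), uk[lev], 0)
      eta <- eta + add
    }
  }
  eta
}

#' @export
predict.cmm <- function(object, newdata = NULL,
                        type = c("link", "response"), re_form = NULL, ...) {
  type <- match.arg(type)
  eta <- cmm_linpred(object, newdata, re_form)
  if (type == "response" && object$family == "binomial") stats::plogis(eta)
  else eta
}

#' @export
residuals.cmm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- predict(object, type = if (object$family == "binomial") "response" else "link")
  r <- object$y - mu
  if (type == "pearson") {
    r <- if (object$family == "binomial") r / sqrt(pmax(mu * (1 - mu), 1e-12))
    else r / sqrt(object$sigma2)
  }
  r
}

#' @export
simulate.cmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    eta <- drop(object$X %*% object$coefficients)
    for (g in names(object$Zlist)) {
      qg <- ncol(object$Zlist[[g]])
      ug <- stats::rnorm(qg, 0, sqrt(object$varcomp[[g]]))
      eta <- eta + drop(object$Zlist[[g]] %*% ug)
    }
    out[[s]] <- if (object$family == "binomial") {
      stats::rbinom(object$n, 1, stats::plogis(eta))
    } else {
      eta + stats::rnorm(object$n, 0, sqrt(object$sigma2))
    }
  }
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}
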