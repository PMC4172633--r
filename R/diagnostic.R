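#' Screen power measures as RHP correlates
#'
#' First step of the two-step analysis: a measure is accepted as a correlate
#' of resource holding potential when its relative-power-difference slope in
#' the victory model is positive \emph{and} its likelihood-ratio test is
#' significant.  A significant negative slope is reported as anomalous —
#' stronger sides losing more often is evidence of a miscoded measure, not
#' of RHP — and never flagged as a correlate.
#'
#' @param victory_fits A list of per-measure victory-model results as
#'   produced inside [run_two_step()]: each element has `measure`,
#'   `slope_raw`, `slope_std` and `lr_test` (a `"cmm_test"` or `NULL`).
#' @param alpha Significance level.
#' @return A data frame with one row per measure: slopes, LR statistic and
#'   p-value, and the flags `is_rhp_correlate`, `anomalous_negative` and
#'   `unscreened` (no LR test available).
#' @export
screen_rhp_correlates <- function(victory_fits, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  rows <- lapply(victory_fits, function(v) {
    has_test <- !is.null(v$lr_test) && is.finite(v$lr_test$p_value)
    p <- if (has_test) v$lr_test$p_value else NA_real_
    stat <- if (has_test) v$lr_test$statistic else NA_real_
    data.frame(measure = v$measure,
               slope_raw = v$slope_raw %||% NA_real_,
               slope_std = v$slope_std %||% NA_real_,
               lr_statistic = stat, p_value = p,
               is_rhp_correlate = has_test && isTRUE(v$slope_std > 0) && p < alpha,
               anomalous_negative = has_test && isTRUE(v$slope_std < 0) && p < alpha,
               unscreened = !has_test)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

sig_pos <- function(x, alpha) isTRUE(x$slope_std > 0) && isTRUE(x$p_value < alpha)
sig_neg <- function(x, alpha) isTRUE(x$slope_std < 0) && isTRUE(x$p_value < alpha)

#' Classify the assessment strategy from a duration slope pattern
#'
#' Applies the sign-pattern decision rules to the winner, loser and relative
#' power slopes of the duration models for one measure, in fixed order:
#'
#' 1. Winner slope significantly negative and loser slope significantly
#'    positive: the mutual-assessment signature — but because opponents that
#'    inflict direct damage (cumulative assessment) mimic it without any
#'    information exchange, the verdict is `mutual-or-CAM`, never proof of
#'    mutual assessment.
#' 2. Both slopes significantly positive: mutual assessment is ruled out
#'    (its diagnostic signal is duration \emph{declining} with winner
#'    power).  If the loser's standardized slope exceeds the winner's the
#'    verdict is `pure-self-assessment`; otherwise `winner-dominated-
#'    attrition`, an extended attrition in which winners persist beyond what
#'    victory requires.
#' 3. Exactly one of the two significantly positive and the other a
#'    positive trend (p below `trend_alpha`): `mutual-ruled-out-attrition`.
#' 4. Otherwise `inconclusive`.
#'
#' The relative-power slope never changes the category — a negative
#' duration/relative-power association can arise spuriously under pure
#' self-assessment — and is recorded in the rationale only.  Any
#' non-converged component model forces `inconclusive` with a warning in
#' the rationale.
#'
#' @param pattern A `"duration_pattern"`: per-predictor lists with
#'   `slope_std`, `p_value` and `converged` for `winner`, `loser` and
#'   `relative`.
#' @param alpha Significance level.
#' @param trend_alpha Trend level (`alpha < trend_alpha < 1`).
#' @return A `"diagnostic_verdict"` list with `measure`, `category`,
#'   `rationale`, `alpha_used`, `trend_alpha_used`.
#' @export
classify_assessment <- function(pattern, alpha = 0.05, trend_alpha = 0.10) {
  stopifnot(alpha > 0, alpha < trend_alpha, trend_alpha < 1)
  w <- pattern$winner; l <- pattern$loser; r <- pattern$relative
  trace <- character(0)
  note <- function(...) trace <<- c(trace, sprintf(...))
  note("winner slope_std = %.4g (p = %.4g); loser slope_std = %.4g (p = %.4g); relative slope_std = %.4g (p = %.4g, recorded only)",
       w$slope_std, w$p_value, l$slope_std, l$p_value,
       r$slope_std %||% NA_real_, r$p_value %||% NA_real_)
  bad <- !isTRUE(w$converged %||% TRUE) || !isTRUE(l$converged %||% TRUE)
  category <- if (bad) {
    note("WARNING: a component model did not converge; verdict forced inconclusive")
    "inconclusive"
  } else if (sig_neg(w, alpha) && sig_pos(l, alpha)) {
    note("rule 1: winner significantly negative, loser significantly positive")
    "mutual-or-CAM"
  } else if (sig_pos(w, alpha) && sig_pos(l, alpha)) {
    note("rule 2: both significantly positive; mutual assessment ruled out")
    if (l$slope_std > w$slope_std) {
      note("loser standardized slope exceeds winner's")
      "pure-self-assessment"
    } else {
      note("winner standardized slope at least as large as loser's")
      "winner-dominated-attrition"
    }
  } else {
    trend_pos <- function(x) isTRUE(x$slope_std > 0) &&
      isTRUE(x$p_value < trend_alpha)
    if ((sig_pos(w, alpha) && !sig_pos(l, alpha) && trend_pos(l)) ||
        (sig_pos(l, alpha) && !sig_pos(w, alpha) && trend_pos(w))) {
      note("rule 3: one side significantly positive, the other a positive trend")
      "mutual-ruled-out-attrition"
    } else {
      note("rule 4: no rule fired")
      "inconclusive"
    }
  }
  structure(list(measure = pattern$measure, category = category,
                 rationale = trace, alpha_used = alpha,
                 trend_alpha_used = trend_alpha),
            class = "diagnostic_verdict")
}

#' @export
print.diagnostic_verdict <- function(x, ...) {
  cat(sprintf("%s: %s  (alpha = %g, trend alpha = %g)\n", x$measure,
              x$category, x$alpha_used, x$trend_alpha_used))
  for (s in x$rationale) cat("  -", s, "\n")
  invisible(x)
}

fit_victory_model <- function(assigned, measure, standardize, control) {
  col <- paste0("rpd_", measure)
  d <- assigned[!is.na(assigned[[col]]), , drop = FALSE]
  d$focal_state <- factor(d$focal_state)
  d$opponent_state <- factor(d$opponent_state)
  sdx <- stats::sd(d[[col]])
  d$x <- if (standardize && sdx > 0) (d[[col]] - mean(d[[col]])) / sdx
  else d[[col]]
  full <- tryCatch(
    cmm(outcome ~ x + (1 | focal_state) + (1 | opponent_state), d,
        family = "binomial", control = control),
    error = function(e) e)
  if (inherits(full, "error"))
    return(list(measure = measure, error = conditionMessage(full)))
  reduced <- cmm(outcome ~ 1 + (1 | focal_state) + (1 | opponent_state), d,
                 family = "binomial", control = control)
  lr <- tryCatch(lr_test(full, reduced), error = function(e) NULL)
  slope_fit <- unname(stats::coef(full)["x"])
  list(measure = measure, fit = full, reduced = reduced, lr_test = lr,
       slope_std = if (standardize && sdx > 0) slope_fit else slope_fit * sdx,
       slope_raw = if (standardize && sdx > 0) slope_fit / sdx else slope_fit,
       n = full$n, converged = full$converged, separation = full$separation)
}

fit_duration_pattern <- function(dyads, measure, standardize, df_method,
                                 control, log_base, rpd_method) {
  design <- build_duration_design(dyads, measure, log_base = log_base,
                                  rpd_method = rpd_method)
  design$winner_state <- factor(design$winner_state)
  design$loser_state <- factor(design$loser_state)
  one <- function(predictor) {
    sdx <- stats::sd(design[[predictor]])
    design$x <- if (standardize && sdx > 0)
      (design[[predictor]] - mean(design[[predictor]])) / sdx
    else design[[predictor]]
    fit <- tryCatch(
      cmm(log10_duration ~ x + (1 | winner_state) + (1 | loser_state),
          design, family = "gaussian", REML = TRUE, control = control),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(list(slope_std = NA_real_, slope_raw = NA_real_,
                  p_value = NA_real_, converged = FALSE,
                  error = conditionMessage(fit)))
    ft <- f_test(fit, "x", df_method = df_method)
    slope_fit <- unname(stats::coef(fit)["x"])
    list(slope_std = if (standardize && sdx > 0) slope_fit else slope_fit * sdx,
         slope_raw = if (standardize && sdx > 0) slope_fit / sdx else slope_fit,
         f_statistic = ft$statistic, df1 = ft$df1, df2 = ft$df2,
         p_value = ft$p_value, method = ft$method,
         converged = fit$converged, fit = fit)
  }
  pattern <- list(measure = measure,
                  winner = one("winner_power"),
                  loser = one("loser_power"),
                  relative = one("relative_power"),
                  n = nrow(design),
                  n_dropped = attr(design, "n_dropped"))
  class(pattern) <- "duration_pattern"
  pattern
}

#' Run the full two-step contest assessment
#'
#' Executes the whole pipeline on a dyad table: balanced focal/opponent
#' assignment, per-measure victory screening (mixed-effects logistic
#' regression of outcome on relative power difference with crossed random
#' intercepts for contestant identity, likelihood-ratio tested), then — for
#' measures passing the screen — three single-predictor Gaussian mixed
#' models of log10 duration on winner, loser and relative power, F-tested
#' with Satterthwaite denominator degrees of freedom, and finally the
#' sign-pattern classification of [classify_assessment()].
#'
#' Winner, loser and relative power of one measure are typically strongly
#' correlated (see [collinearity_report()]), which is why each enters its
#' own model rather than a joint multiple regression.
#'
#' @param dyads A `"contest_dyads"` table.
#' @param measures Measures to analyse; default all measures in the table.
#' @param alpha Significance level for screening and classification.
#' @param trend_alpha Trend level for classification.
#' @param standardize Z-standardize each predictor before fitting (default);
#'   slopes are reported on both the standardized and the raw scale and test
#'   statistics are unaffected.
#' @param screen_gate Only measures passing the victory screen get duration
#'   models (default); set `FALSE` to analyse duration for every measure.
#' @param min_dyads Contract floor on the number of dyads.
#' @param df_method Denominator-degrees-of-freedom method for the duration
#'   F tests (see [f_test()]).
#' @param log_base Base of the duration log transform.
#' @param rpd_method Relative-power formula (see [rpd()]).
#' @param control Optimizer settings ([cmm_control()]).
#' @return A `"two_step_report"` with the balance report, the victory
#'   screen, per-measure duration patterns and diagnostic verdicts.
#' @export
run_two_step <- function(dyads, measures = NULL, alpha = 0.05,
                         trend_alpha = 0.10, standardize = TRUE,
                         screen_gate = TRUE, min_dyads = 10,
                         df_method = "satterthwaite", log_base = 10,
                         rpd_method = c("bounded", "logratio"),
                         control = cmm_control()) {
  stopifnot(is.data.frame(dyads))
  rpd_method <- match.arg(rpd_method)
  if (nrow(dyads) == 0L) stop("empty dyad table")
  if (nrow(dyads) < min_dyads)
    stop("fewer dyads (", nrow(dyads), ") than the configured floor (",
         min_dyads, ")")
  measures <- measures %||% dyad_measures(dyads)
  measures <- tolower(measures)
  assigned <- assign_focal_roles(dyads, rpd_method = rpd_method)
  balance <- balance_check(assigned)
  victory <- lapply(measures, function(m)
    fit_victory_model(assigned, m, standardize, control))
  names(victory) <- measures
  screen <- screen_rhp_correlates(victory, alpha)
  to_analyse <- if (screen_gate) screen$measure[screen$is_rhp_correlate]
  else measures
  patterns <- list(); verdicts <- list()
  for (m in to_analyse) {
    patterns[[m]] <- fit_duration_pattern(dyads, m, standardize, df_method,
                                          control, log_base, rpd_method)
    verdicts[[m]] <- classify_assessment(patterns[[m]], alpha, trend_alpha)
  }
  structure(list(n_dyads = nrow(dyads), measures = measures,
                 balance = balance, victory = victory, screen = screen,
                 no_rhp_correlates = length(to_analyse) == 0L,
                 patterns = patterns, verdicts = verdicts,
                 alpha = alpha, trend_alpha = trend_alpha,
                 screen_gate = screen_gate),
            class = "two_step_report")
}

verdict_table <- function(report) {
  if (!length(report$verdicts))
    return(data.frame(measure = character(0), category = character(0)))
  data.frame(measure = vapply(report$verdicts, `[[`, "", "measure"),
             category = vapply(report$verdicts, `[[`, "", "category"),
             row.names = NULL)
}

#' @export
print.two_step_report <- function(x, ...) {
  cat("Two-step contest assessment —", x$n_dyads, "dyads\n\n")
  print(x$balance)
  cat("\nStep 1 — victory screen (alpha =", x$alpha, "):\n")
  s <- x$screen
  s$slope_raw <- signif(s$slope_raw, 4); s$slope_std <- signif(s$slope_std, 4)
  s$lr_statistic <- signif(s$lr_statistic, 4); s$p_value <- signif(s$p_value, 4)
  print(s, row.names = FALSE)
  if (x$no_rhp_correlates) {
    cat("\n*** NO RHP CORRELATES: no measure passed the victory screen ***\n")
    return(invisible(x))
  }
  cat("\nStep 2 — duration patterns and verdicts:\n")
  for (m in names(x$patterns)) {
    p <- x$patterns[[m]]
    cat(sprintf("  %s (n = %d):\n", m, p$n))
    for (role in c("winner", "loser", "relative")) {
      r <- p[[role]]
      cat(sprintf("    %-8s slope_std = %8.4f  F(%g, %.1f) = %6.3f  p = %.4g\n",
                  role, r$slope_std, r$df1 %||% NA, r$df2 %||% NA,
                  r$f_statistic %||% NA, r$p_value))
    }
    print(x$verdicts[[m]])
  }
  invisible(x)
}

#' @export
summary.two_step_report <- function(object, ...) {
  list(n_dyads = object$n_dyads,
       balance = object$balance,
       screen = object$screen,
       verdicts = verdict_table(object))
}

#' Scatter plots of duration against power
#'
#' Convenience plot of log10 duration against winner, loser and relative
#' power for each analysed measure.
#' @param x A `"two_step_report"`.
#' @param ... Unused.
#' @export
plot.two_step_report <- function(x, ...) {
  ms <- names(x$patterns)
  if (!length(ms)) {
    warning("nothing to plot: no measure passed the victory screen")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(length(ms), 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (m in ms) {
    p <- x$patterns[[m]]
    for (role in c("winner", "loser", "relative")) {
      fit <- p[[role]]$fit
      if (is.null(fit)) { graphics::plot.new(); next }
      graphics::plot(fit$X[, "x"], fit$y,
                     xlab = paste(role, m, "(std)"),
                     ylab = "log10 duration",
                     main = sprintf("%s / %s", m, role))
      graphics::abline(stats::coef(fit)[1], stats::coef(fit)[2], col = 2)
    }
  }
  invisible(x)
}
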