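mk_side <- function(slope, p, converged = TRUE) {
  list(slope_std = slope, p_value = p, converged = converged)
}
mk_pattern <- function(w_slope, w_p, l_slope, l_p, r_slope = -0.1,
                       r_p = 0.5, measure = "cinc") {
  structure(list(measure = measure,
                 winner = mk_side(w_slope, w_p),
                 loser = mk_side(l_slope, l_p),
                 relative = mk_side(r_slope, r_p)),
            class = "duration_pattern")
}

test_that("the decision table maps slope patterns to the documented categories", {
  # both positive, winner at least as strong: the headline attrition pattern
  v <- classify_assessment(mk_pattern(0.4, 0.015, 0.3, 0.02))
  expect_equal(v$category, "winner-dominated-attrition")
  expect_true(any(grepl("ruled out", v$rationale)))
  # both positive, loser stronger: classic self-assessment
  expect_equal(classify_assessment(mk_pattern(0.2, 0.01, 0.5, 0.001))$category,
               "pure-self-assessment")
  # winner negative, loser positive: mutual assessment OR cumulative damage
  expect_equal(classify_assessment(mk_pattern(-0.4, 0.01, 0.4, 0.01))$category,
               "mutual-or-CAM")
  # one significant, the other a positive trend
  expect_equal(classify_assessment(mk_pattern(0.3, 0.01, 0.2, 0.08))$category,
               "mutual-ruled-out-attrition")
  expect_equal(classify_assessment(mk_pattern(0.15, 0.07, 0.4, 0.001))$category,
               "mutual-ruled-out-attrition")
  # nothing fires
  expect_equal(classify_assessment(mk_pattern(0.1, 0.9, 0.1, 0.9,
                                              0.1, 0.9))$category,
               "inconclusive")
})

test_that("the relative-power slope never changes the category", {
  for (r_slope in c(-0.5, 0, 0.5)) for (r_p in c(0.001, 0.9)) {
    expect_equal(classify_assessment(
      mk_pattern(0.4, 0.01, 0.3, 0.02, r_slope, r_p))$category,
      "winner-dominated-attrition")
  }
})

test_that("non-convergence forces an inconclusive verdict with a warning trace", {
  p <- mk_pattern(0.4, 0.001, 0.3, 0.001)
  p$winner$converged <- FALSE
  v <- classify_assessment(p)
  expect_equal(v$category, "inconclusive")
  expect_true(any(grepl("converge", v$rationale)))
})

test_that("verdicts are pure functions of the pattern and thresholds", {
  p <- mk_pattern(0.3, 0.04, 0.2, 0.06)
  v1 <- classify_assessment(p, alpha = 0.05, trend_alpha = 0.10)
  v2 <- classify_assessment(p, alpha = 0.05, trend_alpha = 0.10)
  expect_identical(v1, v2)
  expect_error(classify_assessment(p, alpha = 0.10, trend_alpha = 0.05))
})

test_that("raising alpha moves verdicts toward more specific categories, never away", {
  specificity <- c("inconclusive" = 0, "mutual-ruled-out-attrition" = 1,
                   "pure-self-assessment" = 2,
                   "winner-dominated-attrition" = 2, "mutual-or-CAM" = 2)
  set.seed(99)
  for (i in 1:200) {
    p <- mk_pattern(runif(1, -0.5, 0.5), runif(1),
                    runif(1, -0.5, 0.5), runif(1))
    v_lo <- classify_assessment(p, alpha = 0.02, trend_alpha = 0.06)
    v_hi <- classify_assessment(p, alpha = 0.05, trend_alpha = 0.15)
    expect_gte(specificity[[v_hi$category]], specificity[[v_lo$category]])
  }
})

test_that("the victory screen requires both a positive slope and significance", {
  fits <- list(
    list(measure = "a", slope_raw = 2.1, slope_std = 2.1,
         lr_test = list(statistic = 15, p_value = 1e-4)),
    list(measure = "b", slope_raw = 0.4, slope_std = 0.4,
         lr_test = list(statistic = 1.1, p_value = 0.30)),
    list(measure = "c", slope_raw = -1.5, slope_std = -1.5,
         lr_test = list(statistic = 9, p_value = 0.003)),
    list(measure = "d", slope_raw = 1.0, slope_std = 1.0, lr_test = NULL))
  s <- screen_rhp_correlates(fits, alpha = 0.05)
  expect_equal(s$is_rhp_correlate, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$anomalous_negative, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(s$unscreened, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("all five measures pass the screen when they all load on true RHP", {
  cfg <- contest_sim_config(mode = "WOA", n_contests = 300, n_states = 80,
                            seed = 20)
  r <- run_two_step(simulate_contests(cfg))
  expect_true(all(r$screen$is_rhp_correlate))
  expect_equal(sort(r$screen$measure),
               sort(c("pec", "milper", "tpop", "upop", "cinc")))
})

test_that("generative mechanisms are recovered on fixed seeds", {
  woa <- run_two_step(simulate_contests(
    contest_sim_config(mode = "WOA", n_contests = 200, n_states = 60,
                       seed = 11)), measures = "cinc")
  expect_true(woa$verdicts$cinc$category %in%
                c("pure-self-assessment", "winner-dominated-attrition"))
  sam <- run_two_step(simulate_contests(
    contest_sim_config(mode = "SAM", n_contests = 200, n_states = 60,
                       seed = 11)), measures = "cinc")
  expect_equal(sam$verdicts$cinc$category, "mutual-or-CAM")
})

test_that("the two-step report is invariant to dyad row order", {
  d <- simulate_contests(contest_sim_config(mode = "WOA", n_contests = 80,
                                            n_states = 40, seed = 22))
  r1 <- run_two_step(d, measures = "cinc")
  d2 <- d[rev(seq_len(nrow(d))), ]
  attr(d2, "measures") <- attr(d, "measures")
  r2 <- run_two_step(d2, measures = "cinc")
  expect_equal(r1$verdicts$cinc$category, r2$verdicts$cinc$category)
  expect_equal(r1$screen$p_value, r2$screen$p_value, tolerance = 1e-6)
})

test_that("contract errors: empty tables and configured floors", {
  empty <- make_toy_dyads(durations = numeric(0), war_ids = numeric(0))
  expect_error(run_two_step(empty), "empty")
  small <- make_toy_dyads(durations = c(2, 5))
  expect_error(run_two_step(small), "floor")
})

test_that("failing every screen produces a usable no-correlate report", {
  d <- simulate_contests(contest_sim_config(mode = "NULL", n_contests = 60,
                                            n_states = 40, seed = 30))
  r <- run_two_step(d, measures = "cinc", alpha = 1e-9, trend_alpha = 1e-8)
  expect_true(r$no_rhp_correlates)
  expect_length(r$verdicts, 0)
  expect_output(print(r), "NO RHP CORRELATES")
})
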