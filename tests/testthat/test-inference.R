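test_that("likelihood ratio of identical fixed structures is zero with p = 1", {
  d <- make_gaussian_mixed(42)
  f1 <- cmm(y ~ x + (1 | g1) + (1 | g2), d)
  f2 <- cmm(y ~ x + (1 | g1) + (1 | g2), d)
  expect_warning(t0 <- lr_test(f1, f2), "identical fixed effects")
  expect_equal(t0$statistic, 0, tolerance = 1e-6)
  expect_equal(t0$p_value, 1)
})

test_that("LR tests compare ML fits and are invariant to predictor rescaling", {
  d <- make_gaussian_mixed(42)
  full <- cmm(y ~ x + (1 | g1) + (1 | g2), d)           # REML
  red <- cmm(y ~ 1 + (1 | g1) + (1 | g2), d)
  t1 <- lr_test(full, red)
  expect_equal(t1$method, "LR-chisq")
  expect_equal(t1$df1, 1)
  # the REML objects must have been refitted by ML internally: check against
  # an explicit ML comparison
  full_ml <- cmm(y ~ x + (1 | g1) + (1 | g2), d, REML = FALSE)
  red_ml <- cmm(y ~ 1 + (1 | g1) + (1 | g2), d, REML = FALSE)
  expect_equal(t1$statistic,
               max(0, 2 * (full_ml$loglik - red_ml$loglik)), tolerance = 1e-5)
  # affine rescaling of the predictor leaves the statistic unchanged
  d2 <- d; d2$x <- 100 * d$x - 7
  t2 <- lr_test(cmm(y ~ x + (1 | g1) + (1 | g2), d2), red)
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-4)
})

test_that("non-nested comparisons are contract errors", {
  d <- make_gaussian_mixed(42)
  d$z <- rnorm(nrow(d))
  fx <- cmm(y ~ x + (1 | g1) + (1 | g2), d)
  fz <- cmm(y ~ z + (1 | g1) + (1 | g2), d)
  expect_error(lr_test(fx, fz), "not a subset")
  f1 <- cmm(y ~ x + (1 | g1), d)
  expect_error(lr_test(fx, f1), "random structures")
  db <- make_binomial_mixed(7)
  fb <- cmm(y ~ x + (1 | g1) + (1 | g2), db, family = "binomial")
  expect_error(lr_test(fx, fb), "families")
})

test_that("with no random structure the F test is the classical regression F", {
  set.seed(3)
  d <- data.frame(x = rnorm(25))
  d$y <- 1 + 0.6 * d$x + rnorm(25, 0, 0.8)
  fit <- cmm(y ~ x, d)
  ft <- f_test(fit, "x")
  ref <- summary(lm(y ~ x, d))
  expect_equal(ft$df2, 23)                       # n - p exactly
  expect_equal(ft$statistic, unname(ref$coefficients["x", "t value"]^2),
               tolerance = 1e-8)
  expect_equal(ft$p_value, unname(ref$coefficients["x", "Pr(>|t|)"]),
               tolerance = 1e-8)
})

test_that("Satterthwaite df on a balanced one-random-factor design matches the closed form", {
  # balanced one-way layout, intercept contrast: the Satterthwaite df of the
  # intercept equals the between-groups df (a - 1); the within-cluster
  # covariate slope gets the residual df (n - a ... scale); check against
  # the reference implementation rather than guessing: lmerTest
  set.seed(17)
  a <- 10; r <- 5
  d <- data.frame(g = factor(rep(seq_len(a), each = r)), x = rnorm(a * r))
  d$y <- 1 + 0.5 * d$x + rnorm(a, 0, 0.9)[d$g] + rnorm(a * r, 0, 0.6)
  fit <- cmm(y ~ x + (1 | g), d)
  ft <- f_test(fit, "x")
  ref <- summary(lmerTest::lmer(y ~ x + (1 | g), d))$coefficients
  expect_equal(ft$df2, unname(ref["x", "df"]), tolerance = 0.01)
  expect_equal(ft$statistic, unname(ref["x", "t value"]^2), tolerance = 1e-4)
  expect_equal(ft$p_value, unname(ref["x", "Pr(>|t|)"]), tolerance = 1e-3)
  # intercept contrast: balanced one-way closed form df = a - 1
  fti <- f_test(fit, "(Intercept)")
  expect_equal(fti$df2, a - 1, tolerance = 0.05)
})

test_that("F with one numerator df equals the squared t of the same contrast", {
  d <- make_gaussian_mixed(23)
  fit <- cmm(y ~ x + (1 | g1) + (1 | g2), d)
  ft <- f_test(fit, "x")
  t2 <- (coef(fit)[["x"]] / fit$se[["x"]])^2
  expect_equal(ft$statistic, t2, tolerance = 1e-10)
  expect_equal(ft$df1, 1)
})

test_that("Kenward-Roger requests fall back to Satterthwaite and say so", {
  d <- make_gaussian_mixed(23)
  fit <- cmm(y ~ x + (1 | g1) + (1 | g2), d)
  expect_message(ft <- f_test(fit, "x", df_method = "KR"), "Satterthwaite")
  expect_equal(ft$method, "F-Satterthwaite")
})

test_that("collinearity report flags duplicated and spares independent columns", {
  set.seed(5)
  d <- data.frame(a = rnorm(1000))
  d$b <- d$a
  d$c <- rnorm(1000)
  d$k <- rep(1, 1000)
  rep1 <- collinearity_report(d, c("a", "b", "c"))
  expect_equal(rep1$flagged$r, 1)
  expect_setequal(unlist(rep1$flagged[1, c("col_a", "col_b")]), c("a", "b"))
  expect_lt(abs(rep1$correlations["a", "c"]), 0.1)
  # constant column: undefined, reported, not an error
  rep2 <- collinearity_report(d, c("a", "k"))
  expect_equal(nrow(rep2$undefined), 1)
  expect_error(collinearity_report(d, "a"), "length")
})

test_that("winner, loser and relative power of one measure are collinear in simulated contests", {
  cfg <- contest_sim_config(mode = "WOA", n_contests = 300, n_states = 60,
                            rhp_sdlog = 1, seed = 31)
  des <- build_duration_design(simulate_contests(cfg), "cinc")
  cols <- c("winner_power", "loser_power", "relative_power")
  rep1 <- collinearity_report(des, cols, threshold = 0.25)
  # winner power and the winner-vs-loser contrast share the winner's RHP:
  # flagged, which drives the one-predictor-per-model policy
  expect_true(any(rep1$flagged$col_a == "winner_power" &
                    rep1$flagged$col_b == "relative_power"))
  rep2 <- collinearity_report(des, cols, threshold = 0.25)
  expect_identical(rep1$flagged, rep2$flagged)   # deterministic given the seed
})

test_that("the likelihood-ratio test detects a strong effect essentially always", {
  rej <- logical(30)
  for (i in seq_along(rej)) {
    set.seed(30000 + i)
    d <- data.frame(g1 = factor(sample.int(30, 200, TRUE)),
                    g2 = factor(sample.int(30, 200, TRUE)),
                    x = rnorm(200))
    eta <- 1.5 * d$x + rnorm(30, 0, 0.5)[d$g1] + rnorm(30, 0, 0.5)[d$g2]
    d$y <- rbinom(200, 1, plogis(eta))
    full <- cmm(y ~ x + (1 | g1) + (1 | g2), d, family = "binomial")
    red <- cmm(y ~ 1 + (1 | g1) + (1 | g2), d, family = "binomial")
    rej[i] <- lr_test(full, red)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.99)
})
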