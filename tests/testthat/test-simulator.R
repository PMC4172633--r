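test_that("identical configurations reproduce identical tables", {
  cfg <- contest_sim_config(mode = "SAM", n_contests = 40, seed = 1)
  expect_identical(as.data.frame(simulate_contests(cfg)),
                   as.data.frame(simulate_contests(cfg)))
})

test_that("extending a table does not reshuffle earlier contests", {
  c1 <- contest_sim_config(mode = "WOA", n_contests = 30, seed = 4)
  c2 <- contest_sim_config(mode = "WOA", n_contests = 60, seed = 4)
  d1 <- as.data.frame(simulate_contests(c1))
  d2 <- as.data.frame(simulate_contests(c2))
  expect_equal(d1, d2[seq_len(30), ], ignore_attr = TRUE)
})

test_that("deterministic WOA draw: stronger side wins, duration is the loser's persistence", {
  cfg <- contest_sim_config(mode = "WOA", noise_sd = 0, baseline_scale = 10,
                            persistence_exponent = 1)
  set.seed(1)
  res <- draw_contest(cfg, 3, 1)
  expect_equal(res$winner, 1L)
  expect_equal(res$duration_days, 10)   # a * R_loser^b = 10 * 1
  set.seed(1)
  expect_equal(draw_contest(cfg, 1, 3)$winner, 2L)
})

test_that("CAM with zero damage reduces exactly to the WOA for the same draws", {
  woa <- contest_sim_config(mode = "WOA", seed = 2)
  cam0 <- contest_sim_config(mode = "CAM", damage_rate = 0, seed = 2)
  expect_identical(as.data.frame(simulate_contests(woa))[
    c("winner_state", "loser_state", "duration_days")],
    as.data.frame(simulate_contests(cam0))[
      c("winner_state", "loser_state", "duration_days")])
})

test_that("SAM with equal RHP is a fair coin", {
  cfg <- contest_sim_config(mode = "SAM")
  set.seed(10)
  wins <- replicate(4000, draw_contest(cfg, 2, 2)$winner)
  expect_lt(abs(mean(wins == 1L) - 0.5), 0.025)
})

test_that("dyad tables satisfy their structural invariants", {
  for (mode in c("WOA", "SAM", "CAM", "NULL")) {
    d <- simulate_contests(contest_sim_config(mode = mode, n_contests = 60,
                                              seed = 6))
    expect_true(all(d$winner_state != d$loser_state))
    expect_true(all(d$duration_days >= 1))
    expect_true(all(d$duration_days == round(d$duration_days)))
    expect_true(all(d$winner_cinc >= 0 & d$winner_cinc <= 1))
    expect_true(all(d$loser_cinc >= 0 & d$loser_cinc <= 1))
    for (m in attr(d, "measures"))
      expect_true(all(d[[paste0("winner_", m)]] > 0))
    # identities repeat across contests (the point of the random intercepts)
    expect_lt(length(unique(c(d$winner_state, d$loser_state))), 2 * 60)
  }
})

test_that("stronger-side victory frequency exceeds one half under informative modes", {
  for (mode in c("WOA", "SAM", "CAM")) {
    d <- simulate_contests(contest_sim_config(mode = mode, n_contests = 500,
                                              n_states = 80, seed = 8))
    stronger_won <- mean(d$winner_cinc > d$loser_cinc)
    expect_gt(stronger_won, 0.6)
  }
  d0 <- simulate_contests(contest_sim_config(mode = "NULL", n_contests = 500,
                                             n_states = 80, seed = 8))
  expect_lt(abs(mean(d0$winner_cinc > d0$loser_cinc) - 0.5), 0.08)
})

test_that("large-sample slope signs match each mechanism's fingerprint", {
  # WOA: duration rises with both sides' power, loser's dominating
  d <- simulate_contests(contest_sim_config(mode = "WOA", n_contests = 2000,
                                            n_states = 300, seed = 12))
  des <- build_duration_design(d, "cinc")
  b <- coef(lm(log10_duration ~ scale(winner_power) + scale(loser_power),
               des))
  expect_gt(b[["scale(loser_power)"]], 0)
  expect_gt(b[["scale(winner_power)"]], 0)
  expect_gt(b[["scale(loser_power)"]], b[["scale(winner_power)"]])
  # SAM: duration falls with the absolute relative power difference
  d2 <- simulate_contests(contest_sim_config(mode = "SAM", n_contests = 2000,
                                             n_states = 300, seed = 12))
  des2 <- build_duration_design(d2, "cinc")
  b2 <- coef(lm(des2$log10_duration ~ abs(des2$relative_power)))
  expect_lt(b2[[2]], 0)
  # and winner power shortens contests at fixed loser power
  b3 <- coef(lm(log10_duration ~ scale(winner_power) + scale(loser_power),
                des2))
  expect_lt(b3[["scale(winner_power)"]], 0)
})

test_that("CAM converges in distribution to WOA as damage vanishes", {
  durations <- function(mode, d_rate) {
    cfg <- contest_sim_config(mode = mode, damage_rate = d_rate,
                              n_contests = 1500, n_states = 200, seed = 14,
                              round_days = FALSE)
    simulate_contests(cfg)$duration_days
  }
  woa <- durations("WOA", 0)
  ks <- vapply(c(0.05, 0.5, 2), function(dr)
    unname(stats::ks.test(durations("CAM", dr), woa)$statistic), numeric(1))
  expect_true(all(diff(ks) > 0))   # KS distance to the WOA increases with d
  expect_lt(ks[1], 0.1)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(contest_sim_config(n_states = 1), "n_states")
  expect_error(contest_sim_config(n_contests = 0), "n_contests")
  expect_error(contest_sim_config(baseline_scale = -1), "positive")
  expect_error(contest_sim_config(noise_sd = -0.1), "nonnegative")
  expect_error(contest_sim_config(mode = "FOO"))
})
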