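# Fixture builders shared across the test files.  Everything is generated
# in code under fixed seeds; no data files are stored.

# Gaussian mixed data with two crossed random intercepts
make_gaussian_mixed <- function(seed, n = 80, n1 = 10, n2 = 12,
                                beta0 = 1, slope = 0.8,
                                sd1 = 0.6, sd2 = 0.4, sd_e = 0.5) {
  set.seed(seed)
  d <- data.frame(g1 = factor(sample.int(n1, n, replace = TRUE)),
                  g2 = factor(sample.int(n2, n, replace = TRUE)),
                  x = stats::rnorm(n))
  u1 <- stats::rnorm(n1, 0, sd1)
  u2 <- stats::rnorm(n2, 0, sd2)
  d$y <- beta0 + slope * d$x + u1[d$g1] + u2[d$g2] +
    stats::rnorm(n, 0, sd_e)
  d
}

# Binomial mixed data; one or two crossed factors
make_binomial_mixed <- function(seed, n = 60, n1 = 8, n2 = 9,
                                beta0 = 0.3, slope = 1.2,
                                sd1 = 0.8, sd2 = 0.5, crossed = TRUE) {
  set.seed(seed)
  d <- data.frame(g1 = factor(sample.int(n1, n, replace = TRUE)),
                  x = stats::rnorm(n))
  eta <- beta0 + slope * d$x + stats::rnorm(n1, 0, sd1)[d$g1]
  if (crossed) {
    d$g2 <- factor(sample.int(n2, n, replace = TRUE))
    eta <- eta + stats::rnorm(n2, 0, sd2)[d$g2]
  }
  d$y <- stats::rbinom(n, 1, stats::plogis(eta))
  d
}

# the single-factor oracle fixture scale used against adaptive quadrature:
# 8 groups of 5, moderate random-intercept sd
make_agq_fixture <- function(seed) {
  set.seed(seed)
  d <- data.frame(g = factor(rep(1:8, each = 5)), x = stats::rnorm(40))
  d$y <- stats::rbinom(40, 1, stats::plogis(0.2 + 0.9 * d$x +
                                              stats::rnorm(8, 0, 0.8)[d$g]))
  d
}

# hand-built dyad table (not from the simulator)
make_toy_dyads <- function(durations = c(2, 5, 9, 30),
                           war_ids = seq_along(durations)) {
  n <- length(durations)
  d <- data.frame(war_id = war_ids,
                  winner_state = 100 + seq_len(n),
                  loser_state = 200 + seq_len(n),
                  duration_days = durations,
                  winner_entry_year = 1900 + seq_len(n),
                  loser_entry_year = 1900 + seq_len(n),
                  winner_cinc = seq(0.2, 0.5, length.out = n),
                  loser_cinc = seq(0.1, 0.25, length.out = n))
  attr(d, "measures") <- "cinc"
  class(d) <- c("contest_dyads", "data.frame")
  d
}

# three-war toy COW-dialect file pair: one clean dyadic war, one coalition
# war (3 states), one dyadic stalemate
write_toy_cow_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- function(war, name, code, side, sy, sm, sd, ey, em, ed, out) {
    data.frame(WarNum = war, WarName = name, ccode = code,
               StateName = paste0("S", code), Side = side,
               StartYear1 = sy, StartMonth1 = sm, StartDay1 = sd,
               EndYear1 = ey, EndMonth1 = em, EndDay1 = ed,
               StartYear2 = -8, StartMonth2 = -8, StartDay2 = -8,
               EndYear2 = -8, EndMonth2 = -8, EndDay2 = -8,
               Outcome = out)
  }
  wars <- rbind(
    row(1, "Dyadic", 2, 1, 1900, 1, 1, 1900, 1, 10, 1),
    row(1, "Dyadic", 3, 2, 1900, 1, 1, 1900, 1, 10, 2),
    row(2, "Coalition", 4, 1, 1910, 5, 1, 1910, 8, 1, 1),
    row(2, "Coalition", 5, 1, 1910, 5, 1, 1910, 8, 1, 1),
    row(2, "Coalition", 6, 2, 1910, 5, 1, 1910, 8, 1, 2),
    row(3, "Stalemate", 7, 1, 1920, 2, 1, 1920, 3, 1, 6),
    row(3, "Stalemate", 8, 2, 1920, 2, 1, 1920, 3, 1, 6))
  caps <- data.frame(ccode = c(2, 3, 4, 5, 6, 7, 8),
                     year = c(1900, 1900, 1910, 1910, 1910, 1920, 1920),
                     pec = c(10, 5, 1, 1, 1, 2, 2),
                     milper = c(100, 50, 9, 9, 9, 20, 20),
                     tpop = c(1000, 800, 99, 99, 99, 200, 200),
                     upop = c(300, 200, 9, 9, 9, 50, 50),
                     cinc = c(0.2, 0.1, 0.01, 0.01, 0.01, 0.02, 0.02))
  war_path <- file.path(dir, "toy_wars.csv")
  cap_path <- file.path(dir, "toy_caps.csv")
  utils::write.csv(wars, war_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(caps, cap_path, row.names = FALSE, quote = FALSE)
  list(wars = war_path, capabilities = cap_path)
}
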