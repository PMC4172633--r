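#' Configuration for the dyadic contest simulator
#'
#' Builds a validated configuration for [simulate_contests()].  The simulator
#' emulates the structure of a dyadic interstate-war table: a pool of states
#' with persistent latent fighting ability (RHP), five positive and mutually
#' correlated power measures per state, and one row per contest giving the
#' winner, the loser and a positive duration in days, generated under one of
#' four mechanisms:
#'
#' \describe{
#'   \item{WOA}{War of attrition / pure self-assessment.  Each side persists
#'     for a time \eqn{T_k = a R_k^b \epsilon_k} that depends only on its own
#'     RHP; the side with the smaller persistence loses and the contest lasts
#'     \eqn{\min(T_i, T_j)}.  No information about the opponent is used.}
#'   \item{SAM}{Sequential assessment / mutual assessment.  The stronger side
#'     wins with probability \eqn{\Phi(|RPD|/s)} and the duration
#'     \eqn{a\,e^{-|RPD|/s}\epsilon} shrinks as the relative power difference
#'     grows: well-matched opponents need longer to resolve the contest.}
#'   \item{CAM}{Cumulative assessment.  Self-determined persistence as in the
#'     WOA, but each side's give-up time is shortened by damage inflicted in
#'     proportion to the opponent's RHP:
#'     \eqn{T_k = a R_k^b \epsilon_k / (1 + d R_{opp})}.  With `damage_rate
#'     = 0` this reduces exactly to the WOA for the same random draws.}
#'   \item{NULL}{Fair-coin winner and a duration independent of every power
#'     measure; the diagnostic's false-positive control.}
#' }
#'
#' Latent RHP is log-normal (strictly positive and right-skewed, like
#' national capability data).  Each power measure is
#' \eqn{\exp(\lambda_m \log R + \delta)} with independent Gaussian noise
#' \eqn{\delta} on the log scale, which makes every measure a true correlate
#' of victory with tunable strength and induces positive correlations among
#' the measures.  The `cinc` measure is additionally normalised to a share of
#' the state pool's total so that it lies in \eqn{[0, 1]}.
#'
#' @param mode `"WOA"`, `"SAM"`, `"CAM"` or `"NULL"`.
#' @param n_contests Number of contests (dyads) to generate.
#' @param n_states Size of the state pool; identities are sampled with
#'   replacement across contests so the same state can appear in several
#'   wars, which is what the crossed random intercepts are for.
#' @param rhp_meanlog,rhp_sdlog Location and scale of the persistent
#'   (between-state) component of log latent RHP.
#' @param rhp_within_sd Log-scale sd of the contest-level RHP component: a
#'   state's effective power at the time it enters a war fluctuates around
#'   its persistent level, as real national capabilities do between wars.
#'   Power measures are taken at the contest level (the year-of-entry
#'   analogue), so repeated appearances of a state carry different measure
#'   values while remaining correlated through the persistent component.
#' @param measure_loadings Named vector of per-measure loadings of log RHP;
#'   names fix the measure set.
#' @param measure_noise_sd Log-scale noise sd added to each measure.
#' @param persistence_exponent Elasticity `b` of persistence with respect to
#'   RHP (WOA/CAM).
#' @param sampling_error Assessment noise `s` of the SAM; smaller values mean
#'   sharper mutual assessment.
#' @param damage_rate Damage coefficient `d` of the CAM.
#' @param baseline_scale Baseline duration scale `a` in days.
#' @param noise_sd Log-scale sd of the multiplicative duration noise.
#' @param round_days Round durations up to whole days (default); the day
#'   granularity of real war data.
#' @param seed Integer seed; identical configurations produce identical
#'   tables.  Contests draw from per-contest substreams, so increasing
#'   `n_contests` extends a table without reshuffling earlier contests.
#' @return A `"contest_sim_config"` list.
#' @export
contest_sim_config <- function(mode = c("WOA", "SAM", "CAM", "NULL"),
                               n_contests = 44, n_states = 40,
                               rhp_meanlog = 0, rhp_sdlog = 0.4,
                               rhp_within_sd = 0.4,
                               measure_loadings = c(pec = 1, milper = 1,
                                                    tpop = 1, upop = 1,
                                                    cinc = 1),
                               measure_noise_sd = 0.1,
                               persistence_exponent = 1,
                               sampling_error = 0.35,
                               damage_rate = 0.5,
                               baseline_scale = 30,
                               noise_sd = 0.15,
                               round_days = TRUE,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (n_contests < 1) stop("'n_contests' must be at least 1")
  if (n_states < 2) stop("'n_states' must be at least 2")
  if (is.null(names(measure_loadings)) || any(names(measure_loadings) == ""))
    stop("'measure_loadings' must be a fully named vector")
  for (nm in c("rhp_sdlog", "sampling_error", "baseline_scale"))
    if (get(nm) <= 0) stop("'", nm, "' must be positive")
  if (measure_noise_sd < 0 || noise_sd < 0 || damage_rate < 0 ||
      rhp_within_sd < 0)
    stop("noise and damage parameters must be nonnegative")
  structure(list(mode = mode, n_contests = as.integer(n_contests),
                 n_states = as.integer(n_states),
                 rhp_meanlog = rhp_meanlog, rhp_sdlog = rhp_sdlog,
                 rhp_within_sd = rhp_within_sd,
                 measure_loadings = measure_loadings,
                 measure_noise_sd = measure_noise_sd,
                 persistence_exponent = persistence_exponent,
                 sampling_error = sampling_error,
                 damage_rate = damage_rate,
                 baseline_scale = baseline_scale,
                 noise_sd = noise_sd, round_days = round_days,
                 seed = as.integer(seed)),
            class = "contest_sim_config")
}

#' @export
print.contest_sim_config <- function(x, ...) {
  cat("Contest simulator configuration\n")
  cat("  mode:", x$mode, " contests:", x$n_contests,
      " states:", x$n_states, " seed:", x$seed, "\n")
  cat("  RHP ~ logNormal(", x$rhp_meanlog, ",", x$rhp_sdlog, ")",
      "  measures:", paste(names(x$measure_loadings), collapse = ", "), "\n")
  cat("  a =", x$baseline_scale, " b =", x$persistence_exponent,
      " s =", x$sampling_error, " d =", x$damage_rate,
      " duration noise sd =", x$noise_sd, "\n")
  invisible(x)
}

#' Draw a single contest between two states
#'
#' Generates the winner and duration of one contest under the configured
#' mechanism, given the two sides' latent RHP values.  Uses the current RNG
#' state for its noise draws; [simulate_contests()] wraps it in per-contest
#' substreams.
#'
#' @param config A [contest_sim_config()].
#' @param rhp_i,rhp_j Positive latent RHP of side 1 and side 2.
#' @return A list with `winner` (1 or 2) and `duration_days`.
#' @export
draw_contest <- function(config, rhp_i, rhp_j) {
  stopifnot(inherits(config, "contest_sim_config"),
            rhp_i > 0, rhp_j > 0)
  a <- config$baseline_scale
  b <- config$persistence_exponent
  R <- c(rhp_i, rhp_j)
  if (config$mode %in% c("WOA", "CAM")) {
    d <- if (config$mode == "CAM") config$damage_rate else 0
    eps <- exp(stats::rnorm(2, 0, config$noise_sd))
    persist <- a * R^b * eps / (1 + d * rev(R))
    winner <- which.max(persist)
    duration <- min(persist)
  } else if (config$mode == "SAM") {
    rel <- rpd(rhp_i, rhp_j)
    p_strong <- stats::pnorm(abs(rel) / config$sampling_error)
    strong <- if (rel >= 0) 1L else 2L
    winner <- if (stats::runif(1) < p_strong) strong else 3L - strong
    duration <- a * exp(-abs(rel) / config$sampling_error) *
      exp(stats::rnorm(1, 0, config$noise_sd))
  } else { # NULL
    winner <- if (stats::runif(1) < 0.5) 1L else 2L
    duration <- a * exp(stats::rnorm(1, 0, config$noise_sd))
  }
  if (config$round_days) duration <- max(1, ceiling(duration))
  list(winner = winner, duration_days = duration)
}

#' Simulate a dyadic contest table
#'
#' Draws a pool of states with persistent latent RHP and correlated power
#' measures, then generates `n_contests` contests under the configured
#' mechanism.  Output mirrors the structure of an ingested interstate-war
#' dyad table: one row per contest with winner/loser identities (repeating
#' across contests), a positive integer duration in days, entry years, and
#' the five per-side power measures.
#'
#' @param config A [contest_sim_config()].
#' @return A data frame of class `"contest_dyads"`; the state pool (with
#'   latent RHP and measure values) is attached as attribute `"states"` and
#'   the configuration as `"config"`.
#' @export
simulate_contests <- function(config) {
  stopifnot(inherits(config, "contest_sim_config"))
  measures <- names(config$measure_loadings)
  # state pool: the persistent (between-state) RHP component, substream 0
  set.seed(child_seed(config$seed, 0L))
  log_rhp <- stats::rnorm(config$n_states, config$rhp_meanlog, config$rhp_sdlog)
  states <- data.frame(state_code = 100L + seq_len(config$n_states),
                       state_name = paste0("State", seq_len(config$n_states)),
                       rhp = exp(log_rhp))
  # pool total of the capability-share measure, so cinc stays a share in [0,1]
  cinc_lam <- if ("cinc" %in% measures) config$measure_loadings[["cinc"]] else 1
  cinc_pool <- sum(exp(cinc_lam * log_rhp))
  rows <- vector("list", config$n_contests)
  for (i in seq_len(config$n_contests)) {
    set.seed(child_seed(config$seed, i))
    pair <- sample.int(config$n_states, 2L, replace = FALSE)
    # effective RHP at entry: persistent level times a contest-level shock
    log_rc <- log_rhp[pair] + stats::rnorm(2L, 0, config$rhp_within_sd)
    res <- draw_contest(config, exp(log_rc[1]), exp(log_rc[2]))
    iw <- res$winner; il <- 3L - res$winner
    w <- pair[iw]; l <- pair[il]
    year <- 1823L + (i - 1L) %% 180L
    start_month <- sample.int(12L, 1L)
    start_day <- sample.int(28L, 1L)
    row <- data.frame(war_id = i,
                      war_name = paste0("War", i),
                      winner_state = states$state_code[w],
                      loser_state = states$state_code[l],
                      duration_days = as.numeric(res$duration_days),
                      winner_entry_year = year, loser_entry_year = year,
                      start_year = year, start_month = start_month,
                      start_day = start_day)
    for (m in measures) {
      lam <- config$measure_loadings[[m]]
      val <- exp(lam * log_rc +
                   stats::rnorm(2L, 0, config$measure_noise_sd))
      if (m == "cinc") val <- val / cinc_pool
      row[[paste0("winner_", m)]] <- val[iw]
      row[[paste0("loser_", m)]] <- val[il]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "states") <- states
  attr(out, "config") <- config
  attr(out, "measures") <- measures
  class(out) <- c("contest_dyads", "data.frame")
  out
}

#' @rdname simulate_contests
#' @export
simulate_dataset <- simulate_contests

#' Emit a simulated contest table as Correlates-of-War-dialect files
#'
#' Writes the war-participant and state-year capability tables for a
#' simulated dyad table in the column dialect of the Correlates of War
#' v4.0 Inter-State War and National Material Capabilities files, so the
#' ingestion path can be exercised round-trip on synthetic data.  Numeric
#' power measures are written with 17 significant digits, enough for an
#' exact double-precision round trip.
#'
#' @param dyads A `"contest_dyads"` table from [simulate_contests()].
#' @param dir Output directory (created if needed).
#' @param war_file,cap_file File names inside `dir`.
#' @return Invisibly, a list with the two file paths.
#' @export
write_cow_files <- function(dyads, dir, war_file = "wars.csv",
                            cap_file = "capabilities.csv") {
  stopifnot(inherits(dyads, "contest_dyads"))
  measures <- attr(dyads, "measures")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  start <- as.Date(sprintf("%04d-%02d-%02d", dyads$start_year,
                           dyads$start_month, dyads$start_day))
  end <- start + (dyads$duration_days - 1)
  part <- function(role, side_code, outcome_code) {
    data.frame(
      WarNum = dyads$war_id,
      WarName = dyads$war_name,
      ccode = dyads[[paste0(role, "_state")]],
      StateName = paste0("S", dyads[[paste0(role, "_state")]]),
      Side = side_code,
      StartYear1 = as.integer(format(start, "%Y")),
      StartMonth1 = as.integer(format(start, "%m")),
      StartDay1 = as.integer(format(start, "%d")),
      EndYear1 = as.integer(format(end, "%Y")),
      EndMonth1 = as.integer(format(end, "%m")),
      EndDay1 = as.integer(format(end, "%d")),
      StartYear2 = -8L, StartMonth2 = -8L, StartDay2 = -8L,
      EndYear2 = -8L, EndMonth2 = -8L, EndDay2 = -8L,
      Outcome = outcome_code)
  }
  wars <- rbind(part("winner", 1L, 1L), part("loser", 2L, 2L))
  wars <- wars[order(wars$WarNum, wars$Side), ]
  caps <- list()
  for (role in c("winner", "loser")) {
    block <- data.frame(ccode = dyads[[paste0(role, "_state")]],
                        year = dyads[[paste0(role, "_entry_year")]])
    for (m in measures) block[[m]] <- dyads[[paste0(role, "_", m)]]
    caps[[role]] <- block
  }
  caps <- do.call(rbind, caps)
  caps <- caps[!duplicated(caps[c("ccode", "year")]), ]
  caps <- caps[order(caps$ccode, caps$year), ]
  for (m in measures) caps[[m]] <- sprintf("%.17g", caps[[m]])
  war_path <- file.path(dir, war_file)
  cap_path <- file.path(dir, cap_file)
  utils::write.csv(wars, war_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(caps, cap_path, row.names = FALSE, quote = FALSE)
  invisible(list(wars = war_path, capabilities = cap_path))
}
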