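dyad_measures <- function(dyads) {
  m <- attr(dyads, "measures")
  if (!is.null(m)) return(m)
  sub("^winner_", "", grep("^winner_", names(dyads), value = TRUE))
}

#' Assign balanced focal/opponent roles to contest dyads
#'
#' Before regressing outcome on relative power, each dyad needs an arbitrary
#' but balanced role labelling so that "focal" carries no information about
#' winning.  Dyads are listed by duration (ascending; ties broken by the
#' configured rule) and the winner is alternately designated focal and
#' opponent, starting with focal at rank 1.  For an even number of dyads the
#' focal and opponent sides therefore win exactly equally often; for odd
#' numbers the counts differ by one.  The procedure is deterministic: the
#' same input always yields the same assignment.
#'
#' Each assigned dyad carries the binary outcome (1 if the focal side won)
#' and, for every power measure present on both sides, the signed relative
#' power difference of focal versus opponent (see [rpd()]).
#'
#' @param dyads A `"contest_dyads"` table ([build_dyads()] or
#'   [simulate_contests()]).
#' @param tie_break Ordering rule among equal durations: `"war_id"`
#'   (default, ascending).
#' @param rpd_method Passed to [rpd()].
#' @return An `"assigned_dyads"` data frame: the input columns plus
#'   `focal_state`, `opponent_state`, `outcome`, `duration_rank` and one
#'   `rpd_<measure>` column per measure.
#' @export
assign_focal_roles <- function(dyads, tie_break = c("war_id"),
                               rpd_method = c("bounded", "logratio")) {
  stopifnot(is.data.frame(dyads))
  tie_break <- match.arg(tie_break)
  rpd_method <- match.arg(rpd_method)
  if (nrow(dyads) == 0L) {
    out <- dyads
    out$focal_state <- integer(0); out$opponent_state <- integer(0)
    out$outcome <- integer(0)
    class(out) <- c("assigned_dyads", "data.frame")
    return(out)
  }
  ord <- order(dyads$duration_days, dyads$war_id)
  out <- dyads[ord, , drop = FALSE]
  rank <- seq_len(nrow(out))
  winner_focal <- rank %% 2L == 1L
  out$duration_rank <- rank
  out$focal_state <- ifelse(winner_focal, out$winner_state, out$loser_state)
  out$opponent_state <- ifelse(winner_focal, out$loser_state, out$winner_state)
  out$outcome <- as.integer(winner_focal)
  for (m in dyad_measures(dyads)) {
    wp <- out[[paste0("winner_", m)]]
    lp <- out[[paste0("loser_", m)]]
    fp <- ifelse(winner_focal, wp, lp)
    op <- ifelse(winner_focal, lp, wp)
    ok <- !is.na(fp) & !is.na(op)
    v <- rep(NA_real_, nrow(out))
    v[ok] <- rpd(fp[ok], op[ok], method = rpd_method)
    out[[paste0("rpd_", m)]] <- v
  }
  rownames(out) <- NULL
  attr(out, "measures") <- dyad_measures(dyads)
  class(out) <- c("assigned_dyads", "data.frame")
  out
}

#' Sanity checks on a focal/opponent assignment
#'
#' Reports the number of contests won by the focal and opponent sides, the
#' mean log10 duration of contests won by each, and a Welch two-sample t
#' comparison of the two duration distributions.  The assignment is sound
#' when the win counts are (near) equal and the duration comparison shows no
#' difference.
#'
#' @param assigned An [assign_focal_roles()] result with at least one win
#'   per role for the t comparison.
#' @return A `"balance_report"` list.
#' @export
balance_check <- function(assigned) {
  stopifnot(inherits(assigned, "assigned_dyads"))
  focal_won <- assigned$outcome == 1L
  n_focal <- sum(focal_won); n_opp <- sum(!focal_won)
  ld <- log10(assigned$duration_days)
  mean_focal <- mean(ld[focal_won]); mean_opp <- mean(ld[!focal_won])
  tt <- NULL
  imbalance <- n_focal == 0L || n_opp == 0L
  if (!imbalance && n_focal > 1L && n_opp > 1L)
    tt <- stats::t.test(ld[focal_won], ld[!focal_won])
  structure(list(n_focal_wins = n_focal, n_opponent_wins = n_opp,
                 mean_log10_duration_focal_wins = mean_focal,
                 mean_log10_duration_opponent_wins = mean_opp,
                 welch_t = if (is.null(tt)) NULL else
                   list(statistic = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p_value = tt$p.value),
                 imbalanced = imbalance),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Focal/opponent balance\n")
  cat(sprintf("  wins: focal %d, opponent %d%s\n", x$n_focal_wins,
              x$n_opponent_wins,
              if (x$imbalanced) "  [IMBALANCED: one role never wins]" else ""))
  cat(sprintf("  mean log10 duration of wins: focal %.4f, opponent %.4f\n",
              x$mean_log10_duration_focal_wins,
              x$mean_log10_duration_opponent_wins))
  if (!is.null(x$welch_t))
    cat(sprintf("  Welch t = %.3f (df = %.1f), p = %.3f\n",
                x$welch_t$statistic, x$welch_t$df, x$welch_t$p_value))
  invisible(x)
}

#' Build the duration design for one power measure
#'
#' One row per dyad with both sides' measure present: log10 duration as the
#' response, and winner power, loser power and the winner-versus-loser
#' signed relative power difference as the three predictors (each fitted in
#' its own model downstream), with winner and loser identities as grouping
#' columns for the crossed random intercepts.
#'
#' @param dyads A `"contest_dyads"` table.
#' @param measure Measure name (e.g. `"cinc"`).
#' @param log_base `10` (default) or `exp(1)` for the duration transform.
#' @param rpd_method Passed to [rpd()].
#' @return A `"duration_design"` data frame with columns `war_id`,
#'   `log10_duration`, `winner_power`, `loser_power`, `relative_power`,
#'   `winner_state`, `loser_state`; the number of dyads dropped for a
#'   missing measure is attached as attribute `"n_dropped"`.
#' @export
build_duration_design <- function(dyads, measure, log_base = 10,
                                  rpd_method = c("bounded", "logratio")) {
  stopifnot(is.data.frame(dyads))
  rpd_method <- match.arg(rpd_method)
  wcol <- paste0("winner_", measure); lcol <- paste0("loser_", measure)
  if (is.null(dyads[[wcol]]) || is.null(dyads[[lcol]]))
    stop("measure '", measure, "' not present in the dyad table")
  if (any(dyads$duration_days < 1))
    stop("dyad table contains durations below one day")
  keep <- !is.na(dyads[[wcol]]) & !is.na(dyads[[lcol]])
  d <- dyads[keep, , drop = FALSE]
  out <- data.frame(
    war_id = d$war_id,
    log10_duration = log(d$duration_days, base = log_base),
    winner_power = d[[wcol]],
    loser_power = d[[lcol]],
    relative_power = rpd(d[[wcol]], d[[lcol]], method = rpd_method),
    winner_state = d$winner_state,
    loser_state = d$loser_state)
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("duration_design", "data.frame")
  out
}
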