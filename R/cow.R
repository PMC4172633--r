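#' Column dialect for Correlates-of-War-style tables
#'
#' Describes how to read a pair of delimited files in the Correlates of War
#' v4.0 dialect: the column names of the Inter-State War participant table
#' and the National Material Capabilities table, the outcome-code
#' enumeration, and the missing-value sentinels.  The default matches the
#' v4.0 files; supplying a YAML file with the same structure maps other
#' dataset versions without code changes.
#'
#' @param path Optional YAML file overriding the defaults.
#' @return A `"cow_dialect"` list.
#' @export
cow_dialect <- function(path = NULL) {
  d <- list(
    war = list(
      columns = list(war_id = "WarNum", war_name = "WarName",
                     state_code = "ccode", state_name = "StateName",
                     side = "Side", outcome = "Outcome"),
      start_date = c("StartYear1", "StartMonth1", "StartDay1"),
      end_date = c("EndYear1", "EndMonth1", "EndDay1"),
      outcome_codes = list(won = 1, lost = 2, stalemate = c(3, 6),
                           transformed = 4, other = c(5, 7, 8)),
      sentinels = c(-9, -8)
    ),
    capabilities = list(
      columns = list(state_code = "ccode", year = "year"),
      measures = c(pec = "pec", milper = "milper", tpop = "tpop",
                   upop = "upop", cinc = "cinc"),
      sentinels = c(-9, -8)
    )
  )
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    d <- utils::modifyList(d, ov)
    # yaml collapses the outcome-code lists to generic lists; re-coerce
    d$war$outcome_codes <- lapply(d$war$outcome_codes, as.numeric)
  }
  structure(d, class = "cow_dialect")
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(unlist(cols), names(df))
  if (length(miss))
    stop("missing mandatory column(s) in ", what, ": ",
         paste(miss, collapse = ", "))
}

# Build a Date from year/month/day columns, imputing sentinel month/day to
# mid-year / mid-month (recorded by the caller in the load report).
cow_date <- function(y, m, d, sentinels) {
  y[y %in% sentinels] <- NA
  imputed <- (m %in% sentinels & !is.na(y)) | (d %in% sentinels & !is.na(y))
  m[m %in% sentinels | is.na(m)] <- 6
  d[d %in% sentinels | is.na(d)] <- 15
  out <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  list(date = out, imputed = imputed & !is.na(out))
}

#' Read a Correlates-of-War-dialect war participant table
#'
#' Reads one row per (war, participant), parses entry and exit dates, and
#' maps the source outcome codes to the categories
#' won / lost / stalemate / transformed / other.  Rows whose outcome code is
#' outside the dialect enumeration, or whose dates cannot be parsed or are
#' out of order, are kept in the table flagged `valid = FALSE` and listed in
#' the load report; downstream dyad construction never uses them.
#'
#' @param path CSV file in the configured dialect.
#' @param dialect A [cow_dialect()].
#' @return A `"war_participants"` data frame with columns `war_id`,
#'   `war_name`, `state_code`, `state_name`, `side`, `outcome`,
#'   `entry_date`, `exit_date`, `valid`; the load report (row numbers and
#'   issues) is attached as attribute `"load_report"`.
#' @export
read_war_table <- function(path, dialect = cow_dialect()) {
  if (!file.exists(path)) stop("war table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  wd <- dialect$war
  require_columns(raw, c(wd$columns, wd$start_date, wd$end_date), "war table")
  start <- cow_date(raw[[wd$start_date[1]]], raw[[wd$start_date[2]]],
                    raw[[wd$start_date[3]]], wd$sentinels)
  end <- cow_date(raw[[wd$end_date[1]]], raw[[wd$end_date[2]]],
                  raw[[wd$end_date[3]]], wd$sentinels)
  code <- raw[[wd$columns$outcome]]
  outcome <- rep(NA_character_, nrow(raw))
  for (cat in names(wd$outcome_codes))
    outcome[code %in% wd$outcome_codes[[cat]]] <- cat
  report <- data.frame(row = integer(0), issue = character(0))
  note <- function(rows, issue) {
    if (length(rows))
      report <<- rbind(report, data.frame(row = rows, issue = issue))
  }
  note(which(start$imputed | end$imputed), "date component imputed (sentinel month/day)")
  bad_date <- is.na(start$date) | is.na(end$date)
  note(which(bad_date), "unparseable entry or exit date")
  bad_order <- !bad_date & start$date > end$date
  note(which(bad_order), "entry date after exit date")
  bad_outcome <- is.na(outcome)
  note(which(bad_outcome), "outcome code outside the dialect enumeration")
  out <- data.frame(
    war_id = raw[[wd$columns$war_id]],
    war_name = raw[[wd$columns$war_name]],
    state_code = raw[[wd$columns$state_code]],
    state_name = raw[[wd$columns$state_name]],
    side = raw[[wd$columns$side]],
    outcome = outcome,
    entry_date = start$date,
    exit_date = end$date,
    valid = !(bad_date | bad_order | bad_outcome),
    stringsAsFactors = FALSE)
  attr(out, "load_report") <- report
  class(out) <- c("war_participants", "data.frame")
  out
}

#' Read a Correlates-of-War-dialect capabilities table
#'
#' Reads one row per (state, year) with the five power measures, normalising
#' sentinel missing codes to `NA`.  Duplicate (state, year) keys are a hard
#' error; negative non-sentinel values are set to `NA` and listed in the
#' load report.
#'
#' @param path CSV file in the configured dialect.
#' @param dialect A [cow_dialect()].
#' @return A `"cow_capabilities"` data frame with columns `state_code`,
#'   `year` and one column per measure, plus a `"load_report"` attribute.
#' @export
read_capabilities_table <- function(path, dialect = cow_dialect()) {
  if (!file.exists(path)) stop("capabilities table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cd <- dialect$capabilities
  require_columns(raw, c(cd$columns, cd$measures), "capabilities table")
  out <- data.frame(state_code = raw[[cd$columns$state_code]],
                    year = raw[[cd$columns$year]])
  key <- paste(out$state_code, out$year)
  if (anyDuplicated(key))
    stop("duplicate (state, year) key(s) in capabilities table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  report <- data.frame(row = integer(0), issue = character(0))
  for (m in names(cd$measures)) {
    v <- raw[[cd$measures[[m]]]]
    v[v %in% cd$sentinels] <- NA
    bad <- !is.na(v) & v < 0
    if (any(bad)) {
      report <- rbind(report, data.frame(
        row = which(bad),
        issue = paste0("negative non-sentinel value in '", m, "'")))
      v[bad] <- NA
    }
    out[[m]] <- v
  }
  attr(out, "load_report") <- report
  attr(out, "measures") <- names(cd$measures)
  class(out) <- c("cow_capabilities", "data.frame")
  out
}

#' Look up a state's capabilities in a given year
#'
#' @param caps A [read_capabilities_table()] result.
#' @param state_code,year Key to look up.
#' @return A named numeric vector over the measures; all-`NA` (not an error)
#'   when the key is absent.
#' @export
cap_lookup <- function(caps, state_code, year) {
  measures <- attr(caps, "measures")
  i <- which(caps$state_code == state_code & caps$year == year)
  if (length(i) == 0L)
    return(stats::setNames(rep(NA_real_, length(measures)), measures))
  stats::setNames(as.numeric(caps[i[1], measures]), measures)
}

#' Assemble winner/loser contest dyads from participant records
#'
#' Applies the dyadic-war filters and builds one contest dyad per retained
#' war: exactly two participating states, exactly one coded winner and one
#' coded loser.  Wars ending without a clear outcome (stalemate,
#' transformed, other) and coalition wars are excluded, and every exclusion
#' is listed with its reason.  Duration is counted in days between the
#' war-level start (earliest entry) and end (latest exit); the inclusive
#' convention, under which a war starting and ending on the same date lasts
#' one day, is the default.  Each side is annotated with its capability
#' measures for the year in which it entered the war.  A state with several
#' entry episodes in one war is taken to enter at its earliest entry date.
#'
#' @param wars A [read_war_table()] result.
#' @param caps A [read_capabilities_table()] result.
#' @param missing_policy What to do when a side's capability lookup fails:
#'   `"per-measure"` (default) keeps the dyad with `NA` in the affected
#'   measure so that analyses of other measures retain it; `"drop"` excludes
#'   the dyad entirely.
#' @param day_count `"inclusive"` (default: end - start + 1) or
#'   `"exclusive"` (end - start).
#' @return A `"contest_dyads"` data frame; the exclusion report (war id and
#'   reason) is attached as attribute `"exclusions"`.
#' @export
build_dyads <- function(wars, caps,
                        missing_policy = c("per-measure", "drop"),
                        day_count = c("inclusive", "exclusive")) {
  stopifnot(inherits(wars, "war_participants"),
            inherits(caps, "cow_capabilities"))
  missing_policy <- match.arg(missing_policy)
  day_count <- match.arg(day_count)
  measures <- attr(caps, "measures")
  excl <- data.frame(war_id = numeric(0), reason = character(0))
  exclude <- function(id, reason) {
    excl <<- rbind(excl, data.frame(war_id = id, reason = reason))
    NULL
  }
  dyads <- lapply(split(wars, wars$war_id), function(w) {
    id <- w$war_id[1]
    if (any(!w$valid)) return(exclude(id, "malformed participant row"))
    # collapse multi-episode participants: earliest entry, latest exit
    per_state <- lapply(split(w, w$state_code), function(s) {
      data.frame(state_code = s$state_code[1],
                 outcome = if (length(unique(s$outcome)) == 1L)
                   s$outcome[1] else "inconsistent",
                 entry_date = min(s$entry_date),
                 exit_date = max(s$exit_date))
    })
    per_state <- do.call(rbind, per_state)
    if (nrow(per_state) > 2L) return(exclude(id, "coalition"))
    if (nrow(per_state) < 2L) return(exclude(id, "fewer than two states"))
    n_won <- sum(per_state$outcome == "won")
    n_lost <- sum(per_state$outcome == "lost")
    if (n_won != 1L || n_lost != 1L) {
      if (any(per_state$outcome %in% c("stalemate", "transformed", "other")))
        return(exclude(id, "no-clear-outcome"))
      return(exclude(id, "inconsistent outcome"))
    }
    win <- per_state[per_state$outcome == "won", ]
    los <- per_state[per_state$outcome == "lost", ]
    war_start <- min(per_state$entry_date)
    war_end <- max(per_state$exit_date)
    dur <- as.integer(war_end - war_start) +
      if (day_count == "inclusive") 1L else 0L
    if (dur < 1L) return(exclude(id, "nonpositive duration"))
    d <- data.frame(war_id = id, war_name = w$war_name[1],
                    winner_state = win$state_code,
                    loser_state = los$state_code,
                    duration_days = as.numeric(dur),
                    winner_entry_year = as.integer(format(win$entry_date, "%Y")),
                    loser_entry_year = as.integer(format(los$entry_date, "%Y")))
    wcap <- cap_lookup(caps, win$state_code, d$winner_entry_year)
    lcap <- cap_lookup(caps, los$state_code, d$loser_entry_year)
    if (missing_policy == "drop" && (anyNA(wcap) || anyNA(lcap)))
      return(exclude(id, "missing-capability"))
    for (m in measures) {
      d[[paste0("winner_", m)]] <- wcap[[m]]
      d[[paste0("loser_", m)]] <- lcap[[m]]
    }
    d
  })
  dyads <- do.call(rbind, dyads[!vapply(dyads, is.null, logical(1))])
  if (is.null(dyads)) {
    dyads <- data.frame(war_id = numeric(0))
  } else {
    rownames(dyads) <- NULL
    dyads <- dyads[order(dyads$war_id), ]
  }
  attr(dyads, "exclusions") <- excl
  attr(dyads, "measures") <- measures
  class(dyads) <- c("contest_dyads", "data.frame")
  dyads
}
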