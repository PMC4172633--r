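#' Pipeline configuration
#'
#' Builds and validates the configuration driving the command-style entry
#' points [pipeline_prepare()], [pipeline_analyze()] and
#' [pipeline_validate()].  Exactly one input source must be given: either a
#' pair of real delimited files (war participants + capabilities) or a
#' simulator configuration.
#'
#' @param path Optional YAML file; keys mirror the arguments and are
#'   overridden one-for-one by any argument supplied directly.
#' @param war_file,capabilities_file Input files in the configured dialect.
#' @param dialect_file Optional YAML dialect override (see [cow_dialect()]).
#' @param simulator Either a [contest_sim_config()] or a named list of its
#'   arguments.
#' @param measures Measures to analyse (`NULL`: all available).
#' @param alpha,trend_alpha Significance and trend levels
#'   (`alpha < trend_alpha < 1`).
#' @param standardize,df_method,tie_break,missing_policy,rpd_method
#'   Analysis switches passed through to the pipeline stages.
#' @param out_dir Output directory for the run.
#' @param seed Seed for validation replicates.
#' @param n_replicates Replicates per mode for [pipeline_validate()].
#' @param validate_modes Generative modes exercised by validation.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(path = NULL, war_file = NULL,
                            capabilities_file = NULL, dialect_file = NULL,
                            simulator = NULL, measures = NULL,
                            alpha = 0.05, trend_alpha = 0.10,
                            standardize = TRUE,
                            df_method = "satterthwaite",
                            tie_break = "war_id",
                            missing_policy = "per-measure",
                            rpd_method = "bounded",
                            out_dir = "contest_run", seed = 1L,
                            n_replicates = 100L,
                            validate_modes = c("WOA", "SAM", "NULL")) {
  cfg <- list(war_file = war_file, capabilities_file = capabilities_file,
              dialect_file = dialect_file, simulator = simulator,
              measures = measures, alpha = alpha, trend_alpha = trend_alpha,
              standardize = standardize, df_method = df_method,
              tie_break = tie_break, missing_policy = missing_policy,
              rpd_method = rpd_method, out_dir = out_dir, seed = seed,
              n_replicates = n_replicates, validate_modes = validate_modes)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    supplied <- names(as.list(match.call()))[-1]
    for (k in names(file_cfg))
      if (!(k %in% supplied) && k %in% names(cfg)) cfg[[k]] <- file_cfg[[k]]
  }
  has_files <- !is.null(cfg$war_file) || !is.null(cfg$capabilities_file)
  has_sim <- !is.null(cfg$simulator)
  if (has_files && has_sim)
    stop("configuration must name exactly one input source: real files OR ",
         "a simulator configuration, not both")
  if (has_files && (is.null(cfg$war_file) || is.null(cfg$capabilities_file)))
    stop("real-data input needs both 'war_file' and 'capabilities_file'")
  if (!(cfg$alpha > 0 && cfg$alpha < cfg$trend_alpha && cfg$trend_alpha < 1))
    stop("need 0 < alpha < trend_alpha < 1 (got alpha = ", cfg$alpha,
         ", trend_alpha = ", cfg$trend_alpha, ")")
  if (has_sim && !inherits(cfg$simulator, "contest_sim_config"))
    cfg$simulator <- do.call(contest_sim_config, cfg$simulator)
  structure(cfg, class = "pipeline_config")
}

run_logger <- function(out_dir) {
  log_path <- file.path(out_dir, "log.txt")
  function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
}

write_provenance <- function(config, out_dir) {
  ser <- yaml::as.yaml(unclass(config))
  tmp <- tempfile(); writeLines(ser, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  prov <- list(config_md5 = hash, seed = config$seed,
               r_version = R.version.string,
               package_version = as.character(utils::packageVersion("contestRHP")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(ser, file.path(out_dir, "config_used.yaml"))
  invisible(prov)
}

load_pipeline_dyads <- function(config, log) {
  if (!is.null(config$simulator)) {
    log("simulating %d contests under mode %s (seed %d)",
        config$simulator$n_contests, config$simulator$mode,
        config$simulator$seed)
    return(simulate_contests(config$simulator))
  }
  if (!file.exists(config$war_file %||% ""))
    stop("war table not found: ", config$war_file %||% "<unset>")
  if (!file.exists(config$capabilities_file %||% ""))
    stop("capabilities table not found: ",
         config$capabilities_file %||% "<unset>")
  dialect <- cow_dialect(config$dialect_file)
  wars <- read_war_table(config$war_file, dialect)
  lr <- attr(wars, "load_report")
  for (i in seq_len(nrow(lr))) log("war table row %d: %s", lr$row[i], lr$issue[i])
  caps <- read_capabilities_table(config$capabilities_file, dialect)
  lr <- attr(caps, "load_report")
  for (i in seq_len(nrow(lr)))
    log("capabilities row %d: %s", lr$row[i], lr$issue[i])
  dyads <- build_dyads(wars, caps, missing_policy = config$missing_policy)
  ex <- attr(dyads, "exclusions")
  for (i in seq_len(nrow(ex)))
    log("war %s excluded: %s", ex$war_id[i], ex$reason[i])
  dyads
}

#' Prepare stage: dyad table, role assignment and balance report on disk
#'
#' Ingests (or simulates) the contest data and persists the dyad table, the
#' exclusion report, the focal/opponent assignment and the balance report in
#' the run directory.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the dyad table, assignment and balance
#'   report.
#' @export
pipeline_prepare <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- run_logger(config$out_dir)
  write_provenance(config, config$out_dir)
  dyads <- load_pipeline_dyads(config, log)
  utils::write.csv(as.data.frame(dyads), file.path(config$out_dir, "dyads.csv"),
                   row.names = FALSE)
  ex <- attr(dyads, "exclusions") %||%
    data.frame(war_id = numeric(0), reason = character(0))
  utils::write.csv(ex, file.path(config$out_dir, "exclusions.csv"),
                   row.names = FALSE)
  assigned <- assign_focal_roles(dyads, rpd_method = config$rpd_method)
  utils::write.csv(as.data.frame(assigned),
                   file.path(config$out_dir, "assigned.csv"),
                   row.names = FALSE)
  balance <- balance_check(assigned)
  utils::capture.output(print(balance),
                        file = file.path(config$out_dir, "balance.txt"))
  log("prepared %d dyads (%d exclusions)", nrow(dyads), nrow(ex))
  invisible(list(dyads = dyads, assigned = assigned, balance = balance))
}

report_to_records <- function(report) {
  recs <- list()
  for (i in seq_len(nrow(report$screen))) {
    m <- report$screen$measure[i]
    rec <- as.list(report$screen[i, ])
    p <- report$patterns[[m]]
    if (!is.null(p)) {
      for (role in c("winner", "loser", "relative")) {
        r <- p[[role]]
        rec[[paste0(role, "_slope_std")]] <- r$slope_std
        rec[[paste0(role, "_F")]] <- r$f_statistic %||% NA_real_
        rec[[paste0(role, "_df2")]] <- r$df2 %||% NA_real_
        rec[[paste0(role, "_p")]] <- r$p_value
      }
    }
    v <- report$verdicts[[m]]
    rec$verdict <- if (is.null(v)) NA_character_ else v$category
    rec$rationale <- if (is.null(v)) NA_character_ else
      paste(v$rationale, collapse = " | ")
    recs[[m]] <- rec
  }
  recs
}

#' Analyze stage: run the two-step assessment and persist the report
#'
#' Runs [run_two_step()] on the prepared (or freshly loaded) dyad table and
#' writes the consolidated report in both machine-readable (JSON) and
#' human-readable form.
#'
#' @param config A [pipeline_config()].
#' @param prepared Optional result of [pipeline_prepare()]; when omitted the
#'   prepare stage is run first.
#' @return Invisibly, the `"two_step_report"`.
#' @export
pipeline_analyze <- function(config, prepared = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(prepared)) prepared <- pipeline_prepare(config)
  log <- run_logger(config$out_dir)
  report <- run_two_step(prepared$dyads, measures = config$measures,
                         alpha = config$alpha,
                         trend_alpha = config$trend_alpha,
                         standardize = config$standardize,
                         df_method = config$df_method,
                         rpd_method = config$rpd_method)
  for (m in names(report$patterns)) {
    p <- report$patterns[[m]]
    for (role in c("winner", "loser", "relative"))
      if (!isTRUE(p[[role]]$converged))
        log("measure %s, %s-power duration model did not converge", m, role)
  }
  jsonlite::write_json(report_to_records(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  utils::capture.output(print(report),
                        file = file.path(config$out_dir, "report.txt"))
  log("analysis complete: %d measure(s), %d verdict(s)",
      length(report$measures), length(report$verdicts))
  invisible(report)
}

#' Validate stage: recovery experiment against configured thresholds
#'
#' Runs [recovery_experiment()] for each configured generative mode and
#' evaluates the verdict frequencies against the pass thresholds, writing a
#' confusion table and a pass/fail summary to the run directory.
#'
#' @param config A [pipeline_config()] (the simulator settings are taken
#'   from `config$simulator` when present, otherwise defaults with mode
#'   swapped per run are used).
#' @param thresholds See [recovery_thresholds()]; `NULL` disables threshold
#'   evaluation (smoke mode).
#' @return Invisibly, a list with per-mode `"recovery_report"`s, the checks
#'   table and overall `pass`.
#' @export
pipeline_validate <- function(config, thresholds = recovery_thresholds()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- run_logger(config$out_dir)
  write_provenance(config, config$out_dir)
  base <- config$simulator %||% contest_sim_config(n_contests = 200,
                                                   n_states = 60,
                                                   seed = config$seed)
  reports <- list()
  for (mode in config$validate_modes) {
    cfg <- base; cfg$mode <- mode
    log("recovery: mode %s, %d replicates of %d contests", mode,
        config$n_replicates, cfg$n_contests)
    reports[[mode]] <- recovery_experiment(
      cfg, n_replicates = config$n_replicates,
      measures = config$measures %||% "cinc",
      alpha = config$alpha, trend_alpha = config$trend_alpha)
    utils::capture.output(print(reports[[mode]]),
                          file = file.path(config$out_dir,
                                           paste0("recovery_", mode, ".txt")))
  }
  checks <- NULL; pass <- NA
  if (!is.null(thresholds) && config$n_replicates > 1) {
    checks <- evaluate_recovery(reports, thresholds)
    pass <- all(checks$pass, na.rm = TRUE)
    utils::write.csv(checks, file.path(config$out_dir, "validation_checks.csv"),
                     row.names = FALSE)
    for (i in which(!checks$pass))
      log("FAILED check: %s = %.3f (bound %s %.3f)", checks$check[i],
          checks$value[i], checks$direction[i], checks$bound[i])
    log("validation %s", if (isTRUE(pass)) "PASSED" else "FAILED")
  } else {
    log("smoke mode: thresholds not evaluated")
  }
  invisible(list(reports = reports, checks = checks, pass = pass))
}
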