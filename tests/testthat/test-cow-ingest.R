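test_that("war table reader preserves rows, parses dates and maps outcomes", {
  paths <- write_toy_cow_files(withr::local_tempdir())
  wars <- read_war_table(paths$wars)
  expect_s3_class(wars, "war_participants")
  expect_equal(nrow(wars), 7)
  expect_equal(length(unique(wars$war_id)), 3)
  expect_setequal(unique(wars$outcome), c("won", "lost", "stalemate"))
  expect_equal(wars$entry_date[1], as.Date("1900-01-01"))
  expect_true(all(wars$entry_date <= wars$exit_date))
})

test_that("rows with out-of-enumeration outcome codes are flagged and reported", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  raw <- utils::read.csv(paths$wars)
  raw$Outcome[1] <- 99
  utils::write.csv(raw, paths$wars, row.names = FALSE)
  wars <- read_war_table(paths$wars)
  expect_false(wars$valid[1])
  report <- attr(wars, "load_report")
  expect_true(any(report$row == 1 &
                    grepl("outcome code", report$issue)))
  # the affected war cannot contribute a dyad downstream
  caps <- read_capabilities_table(paths$capabilities)
  dyads <- build_dyads(wars, caps)
  expect_false(1 %in% dyads$war_id)
  expect_true("malformed participant row" %in%
                attr(dyads, "exclusions")$reason)
})

test_that("missing mandatory columns are a configuration error naming the column", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  raw <- utils::read.csv(paths$wars)
  raw$Outcome <- NULL
  utils::write.csv(raw, paths$wars, row.names = FALSE)
  expect_error(read_war_table(paths$wars), "Outcome")
})

test_that("capabilities reader normalises sentinels and handles lookups", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  raw <- utils::read.csv(paths$capabilities)
  raw$upop[1] <- -9
  utils::write.csv(raw, paths$capabilities, row.names = FALSE)
  caps <- read_capabilities_table(paths$capabilities)
  hit <- cap_lookup(caps, 2, 1900)
  expect_true(is.na(hit[["upop"]]))
  expect_equal(hit[["pec"]], 10)        # other measures retained
  miss <- cap_lookup(caps, 999, 1900)   # absent key: NA result, no error
  expect_true(all(is.na(miss)))
  expect_named(miss, c("pec", "milper", "tpop", "upop", "cinc"))
})

test_that("duplicate (state, year) keys are a hard error; negative values reported", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  raw <- utils::read.csv(paths$capabilities)
  expect_silent(read_capabilities_table(paths$capabilities))
  utils::write.csv(rbind(raw, raw[1, ]), paths$capabilities, row.names = FALSE)
  expect_error(read_capabilities_table(paths$capabilities), "duplicate")
  raw$milper[2] <- -5   # negative but not a sentinel
  utils::write.csv(raw, paths$capabilities, row.names = FALSE)
  caps <- read_capabilities_table(paths$capabilities)
  expect_true(is.na(caps$milper[caps$state_code == 3]))
  expect_true(any(grepl("negative non-sentinel",
                        attr(caps, "load_report")$issue)))
})

test_that("dyad construction applies the exclusion filters with reasons", {
  paths <- write_toy_cow_files(withr::local_tempdir())
  wars <- read_war_table(paths$wars)
  caps <- read_capabilities_table(paths$capabilities)
  dyads <- build_dyads(wars, caps)
  expect_equal(nrow(dyads), 1)
  expect_equal(dyads$winner_state, 2)
  expect_equal(dyads$loser_state, 3)
  ex <- attr(dyads, "exclusions")
  expect_equal(nrow(ex), 2)
  expect_setequal(ex$reason, c("coalition", "no-clear-outcome"))
  # accounting invariant: dyads + exclusions = distinct wars
  expect_equal(nrow(dyads) + nrow(ex), length(unique(wars$war_id)))
})

test_that("duration uses the inclusive day count and entry-year capabilities", {
  paths <- write_toy_cow_files(withr::local_tempdir())
  wars <- read_war_table(paths$wars)
  caps <- read_capabilities_table(paths$capabilities)
  dyads <- build_dyads(wars, caps)
  # 1900-01-01 .. 1900-01-10 inclusive is 10 days
  expect_equal(dyads$duration_days, 10)
  expect_equal(build_dyads(wars, caps, day_count = "exclusive")$duration_days, 9)
  expect_equal(dyads$winner_cinc, 0.2)
  expect_equal(dyads$loser_cinc, 0.1)
})

test_that("each side is annotated with capabilities for its own entry year", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  raw <- utils::read.csv(paths$wars)
  # loser enters a year later than the winner
  raw$StartYear1[raw$WarNum == 1 & raw$ccode == 3] <- 1901
  raw$EndYear1[raw$WarNum == 1] <- 1901
  utils::write.csv(raw, paths$wars, row.names = FALSE)
  caps_raw <- utils::read.csv(paths$capabilities)
  caps_raw <- rbind(caps_raw,
                    data.frame(ccode = 3, year = 1901, pec = 7, milper = 60,
                               tpop = 850, upop = 240, cinc = 0.15))
  utils::write.csv(caps_raw, paths$capabilities, row.names = FALSE)
  dyads <- build_dyads(read_war_table(paths$wars),
                       read_capabilities_table(paths$capabilities))
  expect_equal(dyads$winner_entry_year, 1900)
  expect_equal(dyads$loser_entry_year, 1901)
  expect_equal(dyads$winner_cinc, 0.2)   # 1900 value
  expect_equal(dyads$loser_cinc, 0.15)   # 1901 value
})

test_that("missing-capability policy keeps or drops dyads as configured", {
  dir <- withr::local_tempdir()
  paths <- write_toy_cow_files(dir)
  caps_raw <- utils::read.csv(paths$capabilities)
  caps_raw$cinc[caps_raw$ccode == 3] <- -9   # loser cinc missing
  utils::write.csv(caps_raw, paths$capabilities, row.names = FALSE)
  wars <- read_war_table(paths$wars)
  caps <- read_capabilities_table(paths$capabilities)
  kept <- build_dyads(wars, caps, missing_policy = "per-measure")
  expect_equal(nrow(kept), 1)
  expect_true(is.na(kept$loser_cinc))
  expect_equal(kept$loser_pec, 5)   # other measures usable
  dropped <- build_dyads(wars, caps, missing_policy = "drop")
  expect_equal(nrow(dropped), 0)
  expect_true("missing-capability" %in% attr(dropped, "exclusions")$reason)
})

test_that("simulator-emitted files round-trip exactly through ingestion", {
  cfg <- contest_sim_config(mode = "WOA", n_contests = 30, n_states = 15,
                            seed = 5)
  dyads <- simulate_contests(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cow_files(dyads, dir)
  back <- build_dyads(read_war_table(paths$wars),
                      read_capabilities_table(paths$capabilities))
  expect_equal(nrow(back), nrow(dyads))
  cols <- c("war_id", "winner_state", "loser_state", "duration_days",
            "winner_entry_year", "loser_entry_year",
            paste0("winner_", attr(dyads, "measures")),
            paste0("loser_", attr(dyads, "measures")))
  for (cl in cols)
    expect_identical(unname(back[[cl]]), unname(dyads[[cl]]),
                     label = paste("column", cl))
  expect_equal(nrow(attr(back, "exclusions")), 0)
})

test_that("a dialect YAML file reproduces the built-in mapping", {
  d_file <- cow_dialect(system.file("extdata", "cow_v4_dialect.yaml",
                                    package = "contestRHP"))
  d_default <- cow_dialect()
  expect_equal(d_file$war$columns, d_default$war$columns)
  expect_equal(lapply(d_file$war$outcome_codes, as.numeric),
               lapply(d_default$war$outcome_codes, as.numeric))
  expect_equal(names(d_file$capabilities$measures),
               names(d_default$capabilities$measures))
})
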