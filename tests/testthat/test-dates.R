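# Study-day convention, age derivation, offsets, season retention.

test_that("study_day follows the no-day-zero convention", {
  expect_identical(study_day("2020-03-01", "2020-03-01"), 1L)
  expect_identical(study_day("2020-03-05", "2020-03-01"), 5L)
  expect_identical(study_day("2020-02-28", "2020-03-01"), -2L)
  # never zero, strictly monotone in date for a fixed reference
  ref <- as.Date("2020-03-01")
  days <- study_day(ref + (-400:400), ref)
  expect_false(any(days == 0L))
  expect_true(all(diff(days) > 0))
  expect_error(study_day("2020-03", "2020-03-01"), "partial")
  expect_true(is.na(study_day(NA, "2020-03-01")))
})

test_that("derive_age counts completed years with the leap-day rule", {
  expect_identical(derive_age("1950-06-15", "2020-06-14"), 69L)
  expect_identical(derive_age("1950-06-15", "2020-06-15"), 70L)
  # Feb 29 birthday deemed reached on Feb 28 of non-leap years;
  # expected value frozen from the anniversary-enumeration oracle
  expect_identical(oracle_age("2000-02-29", "2021-02-28"), 21L)
  expect_identical(derive_age("2000-02-29", "2021-02-28"), 21L)
  expect_identical(derive_age("2000-02-29", "2021-02-27"), 20L)
  expect_identical(derive_age("2000-02-29", "2024-02-29"), 24L)
  expect_error(derive_age("2020-01-02", "2020-01-01"), "after reference")

  # agreement with the oracle across random pairs
  withr::with_seed(42, {
    dob <- as.Date("1940-01-01") + sample.int(25000, 60)
    ref <- dob + 365L + sample.int(30000, 60)
  })
  expect_identical(derive_age(dob, ref),
                   vapply(seq_along(dob),
                          function(i) oracle_age(dob[i], ref[i]), integer(1)))
  # age increases by at most 1 per one-year step of the reference
  step <- derive_age(dob, as.Date(format(ref, "%Y-%m-%d"))) -
    derive_age(dob, ref - 365L)
  expect_true(all(step %in% c(0L, 1L)))
})

test_that("apply_study_days removes every raw date it transforms", {
  g <- generate_study(50, 4, seed = 5)
  cl <- classify_variables(g$study, default_pipeline_config(1)$classification)
  res <- apply_study_days(g$study, g$study$reference_date, cl)
  out <- res$study
  expect_true("AESTDY" %in% names(out$tables$AE))
  expect_false("AESTDTC" %in% names(out$tables$AE))
  expect_false("RFSTDTC" %in% names(out$tables$DM))
  # full-output scan: zero ISO-date strings in transformed variables
  for (dom in c("AE", "VS", "LB", "DS")) {
    cells <- unlist(out$tables[[dom]], use.names = FALSE)
    expect_identical(sum(grepl("^\\d{4}-\\d{2}-\\d{2}$",
                               cells[!is.na(cells)])), 0L)
  }
  # spot-check the arithmetic against the raw inputs
  ae <- g$study$tables$AE
  ref <- g$truth$reference_dates[ae$SUBJID]
  expect_identical(out$tables$AE$AESTDY,
                   as.character(study_day(ae$AESTDTC, ref)))
  # baseline visit happens on the reference date: day 1, never 0
  expect_true(all(as.integer(out$tables$VS$VSDY) != 0L))
})

test_that("a per-subject reference spec handles missing references by policy", {
  s <- tiny_study()
  s$tables$DM$RFSTDTC[2] <- NA
  cl <- tiny_classification(s)
  ref_err <- list(mode = "per-subject", table = "DM", variable = "RFSTDTC",
                  fallback = "error")
  expect_error(apply_study_days(s, ref_err, cl), "P002")
  ref_drop <- list(mode = "per-subject", table = "DM", variable = "RFSTDTC",
                   fallback = "drop-subject-dates")
  res <- apply_study_days(s, ref_drop, cl)
  expect_true(all(is.na(res$study$tables$AE$AESTDY[2:3])))
  expect_false(is.na(res$study$tables$AE$AESTDY[1]))
})

test_that("partial dates follow the declared imputation policy", {
  s <- tiny_study()
  s$tables$AE$AESTDTC[2] <- "2020-02"
  s$kinds$AE[["AESTDTC"]] <- "partial-date"
  cl <- tiny_classification(s)
  ref <- s$reference_date
  expect_error(apply_study_days(s, ref, cl, partial_policy = "none"),
               "partial")
  mid <- apply_study_days(s, ref, cl, partial_policy = "month-midpoint")
  expect_identical(mid$study$tables$AE$AESTDY[2],
                   as.character(study_day("2020-02-15", "2020-02-01")))
  drop <- apply_study_days(s, ref, cl, partial_policy = "conservative-drop")
  expect_true(is.na(drop$study$tables$AE$AESTDY[2]))
})

test_that("offsets shift each subject's dates rigidly and reproducibly", {
  g <- generate_study(100, 5, seed = 9)
  cl <- classify_variables(g$study, default_pipeline_config(1)$classification)
  a <- offset_dates(g$study, seed = 13, bounds = c(-30, 30),
                    classification = cl)
  b <- offset_dates(g$study, seed = 13, bounds = c(-30, 30),
                    classification = cl)
  expect_identical(a$plan$offsets, b$plan$offsets)
  expect_true(studies_equal(a$study, b$study))
  expect_true(all(a$plan$offsets >= -30 & a$plan$offsets <= 30))
  expect_false(any(a$plan$offsets == 0L))

  # within-subject intervals preserved exactly (AE start vs end)
  ae0 <- g$study$tables$AE; ae1 <- a$study$tables$AE
  gap0 <- as.integer(parse_iso_date(ae0$AEENDTC) - parse_iso_date(ae0$AESTDTC))
  gap1 <- as.integer(parse_iso_date(ae1$AEENDTC) - parse_iso_date(ae1$AESTDTC))
  expect_identical(gap1, gap0)
  # and cross-table: every date of a subject shifts by the same offset
  shift <- as.integer(parse_iso_date(ae1$AESTDTC) - parse_iso_date(ae0$AESTDTC))
  expect_identical(shift, unname(a$plan$offsets[ae0$SUBJID]))

  # constrained: every shifted date within the original trial range, or the
  # subject logged as fallback (date of birth is outside the date rule)
  all_dates <- parse_iso_date(c(
    unlist(lapply(a$study$tables[c("AE", "VS", "LB", "DS")], function(t)
      unlist(t, use.names = FALSE))),
    a$study$tables$DM$RFSTDTC))
  all_dates <- all_dates[!is.na(all_dates)]
  expect_true(all(all_dates >= a$plan$trial_range[1] &
                    all_dates <= a$plan$trial_range[2]))
})

test_that("an infeasible in-range constraint falls back with a warning", {
  # one subject spans the whole trial range: every nonzero offset exits it
  dm <- data.frame(SUBJID = c("P1", "P2"), RFSTDTC = c("2020-01-01", "2020-03-01"))
  vs <- data.frame(SUBJID = c("P1", "P1", "P2"),
                   VSDTC = c("2020-01-01", "2020-06-30", "2020-03-01"))
  s <- new_study(list(DM = dm, VS = vs), subject_key = "SUBJID",
                 kinds = list(DM = c(RFSTDTC = "calendar-date"),
                              VS = c(VSDTC = "calendar-date")))
  cl <- classify_variables(s, list(RFSTDTC = "calendar-date",
                                   VSDTC = "calendar-date",
                                   SUBJID = "subject-identifier"))
  expect_warning(
    r <- offset_dates(s, seed = 2, bounds = c(-10, 10), classification = cl),
    "fallback")
  expect_identical(r$plan$fallback_subjects, "P1")
  expect_true(all(is.na(r$study$tables$VS$VSDTC[1:2])))
  expect_true(any(r$log$rule_id == "dates.offset_fallback"))
  # the unconstrained subject still shifted in range
  expect_false(is.na(r$study$tables$VS$VSDTC[3]))
})

test_that("month and season retention derive calendar categories", {
  s <- tiny_study()
  s$tables$AE$AESTDTC[3] <- "2020-07"           # partial: month recoverable
  s$kinds$AE[["AESTDTC"]] <- "partial-date"
  m <- retain_season(s, "AESTDTC", "month")
  expect_identical(m$study$tables$AE$AESTDTC_MONTH, c("1", "2", "7"))
  sn <- retain_season(s, "AESTDTC", "season")
  expect_identical(sn$study$tables$AE$AESTDTC_SEASON, c("DJF", "DJF", "JJA"))
  expect_error(retain_season(s, "NOPE", "month"), "not found")
  expect_error(retain_season(s, "SEX", "month"), "not a date")
})
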