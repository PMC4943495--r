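# Study container, CSV round trip, and the structural diff used by QC.

write_fixture_csvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("SUBJID,BRTHDTC,SEX",
               "P001,1950-06-15,M",
               "P002,1980-01-02,F"), file.path(dir, "DM.csv"))
  writeLines(c("SUBJID,AESTDTC,AETERM",
               "P001,2020-01-20,headache"), file.path(dir, "AE.csv"))
  c(DM = file.path(dir, "DM.csv"), AE = file.path(dir, "AE.csv"))
}

test_that("read_study assembles domains and enforces the subject key", {
  paths <- write_fixture_csvs(withr::local_tempdir())
  s <- read_study(paths, list(subject_key = "SUBJID",
                              kinds = list(DM = c(BRTHDTC = "calendar-date"))))
  expect_s3_class(s, "trial_study")
  expect_named(s$tables, c("DM", "AE"))
  expect_identical(s$subject_key, "SUBJID")
  expect_identical(nrow(s$tables$DM), 2L)

  # header-only file: 0 records, 3 variables
  dir <- withr::local_tempdir()
  writeLines("SUBJID,AESTDTC,AETERM", file.path(dir, "AE.csv"))
  writeLines(c("SUBJID,SEX", "P001,M"), file.path(dir, "DM.csv"))
  s2 <- read_study(c(DM = file.path(dir, "DM.csv"),
                     AE = file.path(dir, "AE.csv")),
                   list(subject_key = "SUBJID"))
  expect_identical(nrow(s2$tables$AE), 0L)
  expect_identical(ncol(s2$tables$AE), 3L)

  # missing subject key names the offending table
  dir2 <- withr::local_tempdir()
  writeLines(c("USUBJID,SEX", "P001,M"), file.path(dir2, "DM.csv"))
  expect_error(read_study(c(DM = file.path(dir2, "DM.csv")),
                          list(subject_key = "SUBJID")),
               "DM.*SUBJID|SUBJID.*DM")
  expect_error(read_study(stats::setNames(paths, c("DM", "DM")),
                          list(subject_key = "SUBJID")),
               "duplicate domain")
})

test_that("invalid declared dates load as text with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("SUBJID,BRTHDTC", "P001,2010-02-30", "P002,1980-01-02"),
             file.path(dir, "DM.csv"))
  expect_warning(
    s <- read_study(c(DM = file.path(dir, "DM.csv")),
                    list(subject_key = "SUBJID",
                         kinds = list(DM = c(BRTHDTC = "calendar-date")))),
    "do not parse")
  expect_identical(s$tables$DM$BRTHDTC[1], "2010-02-30")
  # independent calendar-validity check over all loaded cells
  parsed <- parse_iso_date(s$tables$DM$BRTHDTC)
  expect_identical(sum(is.na(parsed)), 1L)
})

test_that("write_study/read_study is a lossless round trip", {
  s <- tiny_study()
  s$tables$AE$AETERM[2] <- 'comma, and "quote" and\nnewline'
  dir <- withr::local_tempdir()
  paths <- write_study(s, dir)
  expect_length(paths, 2L)
  s2 <- read_study(paths, list(
    subject_key = "SUBJID", site_key = "SITEID",
    kinds = s$kinds,
    reference_date = s$reference_date))
  expect_true(studies_equal(s, s2))
  expect_identical(s2$tables$AE$AETERM[2], 'comma, and "quote" and\nnewline')

  # collision without overwrite flag is a hard error
  expect_error(write_study(s, dir), "overwrite")
  expect_silent(write_study(s, dir, overwrite = TRUE))

  # 0-record table round trips as a header-only file
  s$tables$AE <- s$tables$AE[0, , drop = FALSE]
  dir2 <- withr::local_tempdir()
  p <- write_study(s, dir2)
  expect_identical(readLines(p[["AE"]])[1], '"SUBJID","AETERM","AEDECOD","AESTDTC"')
  s3 <- read_study(p, list(subject_key = "SUBJID", site_key = "SITEID"))
  expect_identical(nrow(s3$tables$AE), 0L)
})

test_that("round trip holds across generated studies", {
  for (seed in 1:3) {
    g <- generate_study(20, 3, seed = seed,
                        options = list(phi_rate = 0.3,
                                       partial_date_fraction = 0.2))
    dir <- withr::local_tempdir()
    suppressWarnings({
      paths <- write_study(g$study, dir)
      s2 <- read_study(paths, list(subject_key = "SUBJID",
                                   site_key = "SITEID",
                                   kinds = g$study$kinds))
    })
    expect_true(studies_equal(g$study, s2))
  }
})

test_that("diff_studies reports exactly the changed (table, variable) pairs", {
  s <- tiny_study()
  expect_identical(nrow(diff_studies(s, s)), 0L)

  dropped <- s
  dropped$tables$DM$BRTHDTC <- NULL
  d <- diff_studies(s, dropped)
  expect_identical(d$table, "DM")
  expect_identical(d$variable, "BRTHDTC")
  expect_identical(d$kind, "removed")

  recoded <- s
  for (dom in names(recoded$tables)) {
    x <- recoded$tables[[dom]]$SUBJID
    recoded$tables[[dom]]$SUBJID <- paste0("X", x)
  }
  recoded$tables$DM$SUBJID <- paste0("X", s$tables$DM$SUBJID)
  d2 <- diff_studies(s, recoded)
  expect_setequal(d2$table, c("DM", "AE"))
  expect_true(all(d2$variable == "SUBJID"))
  expect_true(all(d2$kind == "recoded"))

  mismatched <- s
  names(mismatched$tables)[2] <- "VS"
  names(mismatched$kinds)[2] <- "VS"
  expect_error(diff_studies(s, mismatched), "AE")
})

test_that("any single-variable mutation yields exactly one diff entry", {
  s <- tiny_study()
  cases <- list(
    function(x) { x$tables$DM$SEX[1] <- "F"; x },                 # value edit
    function(x) { x$tables$AE$AETERM <- NA_character_; x },       # blanked
    function(x) { x$tables$DM$NEWCOL <- c("a", "b", "c"); x },    # added
    function(x) { x$tables$AE$AEDECOD <- NULL; x })               # removed
  expected <- list(c("DM", "SEX"), c("AE", "AETERM"),
                   c("DM", "NEWCOL"), c("AE", "AEDECOD"))
  for (i in seq_along(cases)) {
    d <- diff_studies(s, cases[[i]](s))
    expect_identical(nrow(d), 1L)
    expect_identical(c(d$table, d$variable), expected[[i]])
  }
})

test_that("study invariants reject orphan subjects and bad structure", {
  dm <- data.frame(SUBJID = "P001", SEX = "M")
  ae <- data.frame(SUBJID = c("P001", "P999"), AETERM = c("a", "b"))
  expect_error(new_study(list(DM = dm, AE = ae), subject_key = "SUBJID"),
               "P999")
  expect_error(new_study(list(DM = dm, DM = dm), subject_key = "SUBJID"),
               "duplicate domain")
})
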