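# Safe Harbor registry, declaration-driven classification, cell scanner.

test_that("the registry holds exactly the eighteen identifier classes", {
  reg <- builtin_registry()
  expect_identical(nrow(reg), 18L)
  expect_identical(reg$code, sort(reg$code))
  expect_false(anyDuplicated(reg$code) > 0)
  expect_identical(reg$label[reg$code == "F"], "Email addresses")
  expect_identical(reg$label[reg$code == "D"], "Telephone numbers")
  expect_match(reg$label[reg$code == "C"], "dates")
  # the "no actual knowledge" condition rides along as an attestation
  expect_match(attr(reg, "attestation"), "actual knowledge")
  # immutability: a second call is unaffected by mutating the first copy
  reg$label[1] <- "tampered"
  expect_identical(builtin_registry()$label[1], "Name")
})

test_that("classification applies role defaults and invariants", {
  s <- tiny_study()
  cl <- classify_variables(s, list(BRTHDTC = "date-of-birth",
                                   SUBJID = "subject-identifier"))
  expect_identical(cl$BRTHDTC$hipaa_class, "direct")
  expect_identical(cl$BRTHDTC$registry_code, "C")
  expect_identical(cl$BRTHDTC$retain_policy, "transform")
  expect_identical(cl$SUBJID$hipaa_class, "direct")
  expect_identical(cl$SUBJID$retain_policy, "recode")

  # totality: every variable classified; undeclared -> review set
  all_vars <- unique(unlist(lapply(s$tables, names)))
  expect_setequal(names(cl), all_vars)
  expect_true("SEX" %in% attr(cl, "needs_review"))
  expect_identical(cl$SEX$role, "other")
  expect_identical(cl$SEX$retain_policy, "keep")

  expect_error(classify_variables(s, list(XYZCOL = "measurement")), "XYZCOL")
  # a direct identifier may not be kept
  expect_error(classify_variables(s, list(SEX = list(
    role = "other", hipaa_class = "direct", retain_policy = "keep"))),
    "removed, recoded or transformed")
  # a registry code implies direct classification
  expect_error(classify_variables(s, list(SEX = list(
    role = "other", hipaa_class = "none", registry_code = "A",
    retain_policy = "keep"))), "direct")
})

test_that("the scanner finds pattern families with exact spans", {
  tab <- data.frame(NOTE = c("contact john.doe@example.com",
                             "BP 120/80 at visit 3",
                             "call 555-867-5309 or fax",
                             "ssn 123-45-6789 on file",
                             "see https://example.org/x and 10.0.0.1",
                             "zip 02138-1234 recorded",
                             "seen 2020-03-01 in clinic",
                             NA))
  f <- scan_free_values(tab)
  expect_identical(sort(unique(f$family)),
                   sort(c("email", "phone", "ssn-like", "url", "ip",
                          "zip-like", "date-like")))
  em <- f[f$family == "email", ]
  expect_identical(em$record, 1L)
  expect_identical(em$registry_code, "F")
  expect_identical(substr(tab$NOTE[1], em$start, em$end),
                   "john.doe@example.com")
  # no findings on plain clinical text
  expect_identical(nrow(scan_free_values(tab[2, , drop = FALSE])), 0L)
  # determinism
  expect_identical(f, scan_free_values(tab))
  expect_error(scan_free_values(tab, families = "nope"), "unknown pattern")
})

test_that("scanner recall on planted identifiers is complete", {
  g <- generate_study(400, 5, seed = 11,
                      options = list(phi_rate = 0.25,
                                     phi_families = c("email", "phone")))
  truth <- g$truth$planted
  expect_gt(nrow(truth), 30)
  f <- scan_free_values(g$study$tables$AE, variables = "AETERM",
                        families = c("email", "phone"))
  # every plant is found at its coordinates with the right family
  for (i in seq_len(nrow(truth))) {
    hit <- f[f$record == truth$record[i] & f$family == truth$family[i], ]
    expect_gte(nrow(hit), 1L)
    expect_true(truth$value[i] %in% hit$match)
  }
  # and nothing beyond the plants fires in those families: exact count
  expect_identical(nrow(f), nrow(truth))
})

test_that("scan_study scans every domain and reports table coordinates", {
  g <- generate_study(30, 3, seed = 2)
  f <- scan_study(g$study, families = c("email", "ssn-like"))
  expect_true(all(c("table", "variable", "record") %in% names(f)))
  # the planted DM identifier columns are caught
  expect_true(any(f$table == "DM" & f$variable == "EMAIL"))
  expect_true(any(f$table == "DM" & f$variable == "SSN"))
})
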