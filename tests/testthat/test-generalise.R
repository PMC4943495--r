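# Age top-coding and binning, race mapping, pooling, ZIP truncation.

test_that("age top-coding caps strictly above 89", {
  expect_identical(cap_age(89), "89")
  expect_identical(cap_age(90), ">89")
  expect_identical(cap_age(0), "0")
  expect_identical(cap_age(c(88, 89, 90, 120, NA)),
                   c("88", "89", ">89", ">89", NA))
  expect_error(cap_age(-1), "negative")
  # idempotent, including on already-capped labels
  once <- cap_age(c(85, 95))
  expect_identical(cap_age(once), once)
  # configurable label
  expect_identical(cap_age(92, label = "90 or older"), "90 or older")
  expect_error(cap_age(c("85", "eighty")), "non-numeric")
})

test_that("binning uses left-closed right-open fixed-width bins", {
  five <- bin_spec(5)
  expect_identical(bin_value(67, five), "65-69")
  expect_identical(bin_value(65, five), "65-69")   # left edge included
  expect_identical(bin_value(64, five), "60-64")   # right edge excluded
  expect_identical(bin_value(0, five), "0-4")
  ten <- bin_spec(10, style = "decimal")
  expect_identical(bin_value(72.4, ten), "70-79.9")
  expect_identical(bin_value(c(45, 120.0), ten), c("40-49.9", "120-129.9"))
  # idempotent on already-binned labels; non-finite -> missing, recorded
  expect_identical(bin_value("65-69", five), "65-69")
  out <- bin_value(c("67", "not a number", NA), five)
  expect_identical(as.character(out), c("65-69", NA, NA))
  expect_identical(attr(out, "unbinned"), 2L)
  expect_error(bin_spec(0), "width")
})

test_that("race maps into the FDA categories with a review route", {
  expect_identical(as.character(map_race("BLACK")), "Black or African American")
  expect_identical(as.character(map_race("WHITE")), "White")
  expect_identical(as.character(map_race(" white ")), "White")
  out <- map_race(c("ASIAN", "MARTIAN"))
  expect_identical(as.character(out), c("Asian", NA))
  expect_identical(attr(out, "unmapped"), "MARTIAN")
  # image lies within the declared category set plus missing
  fda <- c("American Indian or Alaska Native", "Asian",
           "Black or African American",
           "Native Hawaiian or Other Pacific Islander", "White",
           "Other/Multiple")
  mapped <- map_race(c("WHITE", "BLACK", "CAUCASIAN", "MULTIPLE",
                       "OTHER", "ASIAN", "XENO"))
  expect_true(all(is.na(mapped) | mapped %in% fda))
})

test_that("pooling counts distinct subjects, not rows", {
  # site A: 50 subjects, B: 2, C: 1 — with duplicate rows per subject
  tab <- data.frame(
    SUBJID = c(sprintf("A%02d", 1:50), "B1", "B2", "B2", "C1", "C1"),
    SITE = c(rep("A", 50), "B", "B", "B", "C", "C"))
  r <- pool_rare_categories(tab, "SITE", "SUBJID", min_count = 5,
                            pooled_label = "POOLED")
  expect_identical(unname(r$mapping[c("A", "B", "C")]),
                   c("A", "POOLED", "POOLED"))
  expect_identical(unique(r$table$SITE[tab$SITE %in% c("B", "C")]), "POOLED")
  expect_identical(unique(r$table$SITE[tab$SITE == "A"]), "A")
  # oracle agreement + conservation of subject counts
  oc <- brute_category_counts(tab, "SITE", "SUBJID")
  post <- brute_category_counts(r$table, "SITE", "SUBJID")
  expect_identical(unname(post["POOLED"]), unname(oc["B"] + oc["C"]))
  expect_true(all(post[names(post) != "POOLED"] >= 5))

  # nothing rare: identity mapping
  r2 <- pool_rare_categories(tab[1:50, ], "SITE", "SUBJID", min_count = 5)
  expect_identical(r2$mapping, c(A = "A"))
  # sole category below threshold: vacuous, warned
  solo <- data.frame(SUBJID = c("X1", "X2", "X3"), SITE = "Z")
  expect_warning(pool_rare_categories(solo, "SITE", "SUBJID", min_count = 5),
                 "vacuous")
  expect_error(pool_rare_categories(tab, "NOPE", "SUBJID"), "not found")
})

test_that("pooling leaves every surviving category at or above the floor", {
  for (seed in 1:5) {
    g <- random_qi_study(80, seed)
    tab <- g$tables$DM
    r <- pool_rare_categories(tab, "SITEID", "SUBJID", min_count = 10)
    counts <- brute_category_counts(r$table, "SITEID", "SUBJID")
    expect_true(all(counts[names(counts) != "POOLED"] >= 10))
  }
})

test_that("ZIP truncation retains exactly three digits when permitted", {
  expect_identical(truncate_zip("02138", retention_permitted = TRUE), "021**")
  expect_identical(truncate_zip("02138", retention_permitted = FALSE),
                   NA_character_)
  expect_identical(truncate_zip("02138-1234", retention_permitted = TRUE),
                   "021**")
  out <- truncate_zip(c("2138", "abcde", "02138"), retention_permitted = TRUE)
  expect_identical(as.character(out), c(NA, NA, "021**"))
  expect_identical(attr(out, "malformed"), c(1L, 2L))
})
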