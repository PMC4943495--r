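# Random re-coding: consistency, injectivity, determinism, lifecycle.

test_that("subject re-coding is consistent across tables and injective", {
  s <- tiny_study()
  r <- remap_subjects(s, seed = 7, template = "S####")
  key <- r$key
  expect_identical(sort(names(key$entries)), c("P001", "P002", "P003"))
  expect_identical(length(unique(key$entries)), 3L)           # injective
  expect_false(any(key$entries %in% names(key$entries)))      # new != old
  # AE rows for P002 carry the same new code as P002's DM row
  new_p002 <- unname(key$entries[["P002"]])
  expect_identical(r$study$tables$AE$SUBJID[2:3], rep(new_p002, 2))
  expect_identical(r$study$tables$DM$SUBJID[2], new_p002)
  # induced mapping identical across every table pair
  for (dom in names(s$tables)) {
    old <- s$tables[[dom]]$SUBJID
    new <- r$study$tables[[dom]]$SUBJID
    expect_identical(new, unname(key$entries[old]))
  }
})

test_that("re-coding is deterministic given the seed and varies across seeds", {
  s <- tiny_study()
  a <- remap_subjects(s, seed = 7, template = "S####")
  b <- remap_subjects(s, seed = 7, template = "S####")
  expect_identical(a$key$entries, b$key$entries)
  expect_true(studies_equal(a$study, b$study))
  keys <- vapply(1:100, function(sd)
    paste(remap_subjects(s, seed = sd, template = "S####")$key$entries,
          collapse = "|"), character(1))
  expect_gte(length(unique(keys)), 99L)
})

test_that("the template space must fit the identifier count", {
  s <- tiny_study()
  expect_error(remap_subjects(s, seed = 1, template = "S"), "#")
  g <- generate_study(30, 3, seed = 3)
  expect_error(remap_subjects(g$study, seed = 1, template = "S#"),
               "template")
})

test_that("site re-coding randomises codes at site scope", {
  s <- tiny_study()
  r <- remap_sites(s, seed = 5)
  expect_identical(r$key$scope, "site")
  expect_identical(sort(names(r$key$entries)), c("1001", "1002"))
  expect_identical(length(unique(r$key$entries)), 2L)
  expect_identical(r$study$tables$DM$SITEID,
                   unname(r$key$entries[s$tables$DM$SITEID]))
  # single-site study: one entry
  s1 <- s
  s1$tables$DM$SITEID <- "1001"
  expect_length(remap_sites(s1, seed = 5)$key$entries, 1L)
  s$site_key <- NULL
  expect_error(remap_sites(s, seed = 5), "site key")
})

test_that("a prior code key keeps extension studies consistent", {
  s <- tiny_study()
  first <- remap_subjects(s, seed = 7, template = "S####")
  ext <- s
  ext$tables$DM <- rbind(ext$tables$DM,
                         data.frame(SUBJID = "P004", SITEID = "1002",
                                    BRTHDTC = "1990-05-05", SEX = "M",
                                    RFSTDTC = "2020-04-01"))
  second <- remap_subjects(ext, seed = 99, template = "S####",
                           prior_key = first$key)
  expect_identical(second$key$entries[c("P001", "P002", "P003")],
                   first$key$entries[c("P001", "P002", "P003")])
  expect_false(second$key$entries[["P004"]] %in% first$key$entries)
  destroyed <- destroy_key(first$key)
  expect_error(remap_subjects(ext, seed = 1, prior_key = destroyed), "active")
})

test_that("destroying a key erases entries but keeps the attestation", {
  s <- tiny_study()
  key <- remap_subjects(s, seed = 7)$key
  old_codes <- names(key$entries); new_codes <- unname(key$entries)
  d <- destroy_key(key)
  expect_identical(d$status, "destroyed")
  expect_length(d$entries, 0L)
  expect_identical(d$attestation$event, c("created", "destroyed"))
  path <- withr::local_tempfile(fileext = ".json")
  write_code_key(d, path)
  txt <- paste(readLines(path), collapse = "")
  for (code in c(old_codes, new_codes))
    expect_false(grepl(code, txt, fixed = TRUE))
  expect_warning(d2 <- destroy_key(d), "already destroyed")
  expect_identical(d2$status, "destroyed")
})

test_that("assignments carry no information from the records", {
  g <- generate_study(120, 4, seed = 21)
  r <- remap_subjects(g$study, seed = 31)
  cov <- g$truth$covariates
  new_rank <- rank(unname(r$key$entries[cov$SUBJID]))
  p_age <- perm_test_cor(new_rank, cov$AGE, n_resamples = 500, seed = 3)
  p_site <- perm_test_cor(new_rank, as.integer(factor(cov$SITEID)),
                          n_resamples = 500, seed = 4)
  expect_gt(p_age, 0.01)
  expect_gt(p_site, 0.01)
})

test_that("seed fingerprints are stable one-way digests", {
  expect_identical(fingerprint(42), fingerprint(42))
  expect_false(fingerprint(42) == fingerprint(43))
  expect_match(fingerprint("abc"), "^[0-9a-f]{16}$")
  key <- remap_subjects(tiny_study(), seed = 12)$key
  expect_false(grepl("12", key$seed_fingerprint, fixed = TRUE) &&
                 key$seed_fingerprint == "12")
})
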