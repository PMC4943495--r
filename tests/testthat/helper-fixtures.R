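# Shared fixtures and independent oracles. The oracles here are deliberately
# naive (loops, pairwise comparison, enumeration) and never call the code
# paths they check.

tiny_study <- function() {
  dm <- data.frame(
    SUBJID = c("P001", "P002", "P003"),
    SITEID = c("1001", "1001", "1002"),
    BRTHDTC = c("1950-06-15", "1980-01-02", "2000-02-29"),
    SEX = c("M", "F", "F"),
    RFSTDTC = c("2020-01-10", "2020-02-01", "2020-03-15"))
  ae <- data.frame(
    SUBJID = c("P001", "P002", "P002"),
    AETERM = c("terrible headache after seeing Dr. Smith",
               "mild nausea", "dizzy spells"),
    AEDECOD = c("Headache", "Nausea", "Dizziness"),
    AESTDTC = c("2020-01-20", "2020-02-05", "2020-02-20"))
  new_study(list(DM = dm, AE = ae), subject_key = "SUBJID",
            site_key = "SITEID",
            kinds = list(DM = c(BRTHDTC = "calendar-date",
                                RFSTDTC = "calendar-date"),
                         AE = c(AESTDTC = "calendar-date")),
            reference_date = list(mode = "per-subject", table = "DM",
                                  variable = "RFSTDTC"))
}

tiny_classification <- function(study) {
  classify_variables(study, list(
    SUBJID = "subject-identifier", SITEID = "site-identifier",
    BRTHDTC = "date-of-birth", RFSTDTC = "calendar-date",
    AESTDTC = "calendar-date", AETERM = "verbatim-text",
    AEDECOD = "coded-term", SEX = "quasi-identifier"))
}

# brute-force equivalence classes by pairwise row comparison (missing equal
# only to missing); independent of the hash-key grouping in the package
brute_equiv_sizes <- function(df) {
  m <- as.matrix(df)
  n <- nrow(m)
  if (n == 0L) return(integer(0))
  assigned <- rep(NA_integer_, n)
  cls <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cls <- cls + 1L
    eq <- rep(TRUE, n)
    for (k in seq_len(ncol(m))) {
      a <- m[i, k]; b <- m[, k]
      eq <- eq & if (is.na(a)) is.na(b) else (!is.na(b) & b == a)
    }
    assigned[is.na(assigned) & eq] <- cls
  }
  sort(as.integer(table(assigned)))
}

# brute-force distinct-subject count per category
brute_category_counts <- function(tab, var, key) {
  cats <- unique(tab[[var]][!is.na(tab[[var]])])
  out <- integer(0)
  for (ct in cats) {
    subs <- character(0)
    for (r in seq_len(nrow(tab)))
      if (!is.na(tab[[var]][r]) && tab[[var]][r] == ct)
        subs <- union(subs, tab[[key]][r])
    out[ct] <- length(subs)
  }
  out
}

# completed-years age by anniversary enumeration (Feb 29 birthdays deemed
# reached on Feb 28 of non-leap years)
oracle_age <- function(dob, ref) {
  dob <- as.Date(dob); ref <- as.Date(ref)
  is_leap <- function(y) (y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0
  dl <- as.POSIXlt(dob)
  count <- 0L
  for (y in (dl$year + 1901):(as.POSIXlt(ref)$year + 1900)) {
    m <- dl$mon + 1L; d <- dl$mday
    if (m == 2L && d == 29L && !is_leap(y)) d <- 28L
    ann <- as.Date(sprintf("%04d-%02d-%02d", y, m, d))
    if (ann <= ref) count <- count + 1L
  }
  count
}

# two-sided permutation test on |Pearson correlation|
perm_test_cor <- function(x, y, n_resamples = 1000, seed = 7) {
  obs <- abs(stats::cor(x, y))
  withr::with_seed(seed, {
    perm <- replicate(n_resamples, abs(stats::cor(x, sample(y))))
  })
  (sum(perm >= obs) + 1) / (n_resamples + 1)
}

# a quick random subject-level study for oracle-equivalence sweeps
random_qi_study <- function(n, seed) {
  withr::with_seed(seed, {
    dm <- data.frame(
      SUBJID = sprintf("R%04d", seq_len(n)),
      SITEID = as.character(sample(1:4, n, replace = TRUE)),
      AGEGR = sample(c("18-39", "40-64", "65+", NA), n, replace = TRUE),
      SEX = sample(c("M", "F", NA), n, replace = TRUE),
      COUNTRY = sample(c("USA", "DEU", "JPN"), n, replace = TRUE))
    new_study(list(DM = dm), subject_key = "SUBJID", site_key = "SITEID")
  })
}
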