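# Synthetic multi-domain trial fixture generator. Produces DM/AE/VS/LB/DS
# tables with planted direct identifiers and a ground-truth manifest so every
# transform, scanner and risk metric can be exercised without real data.
# Fixtures are built to hit rule boundaries (ages up to 95 for the >89 cap,
# rare coded events, partial dates on request), not to be clinically
# realistic.

syn_phi_value <- function(family, i) {
  fn <- SYN_FIRST_NAMES[(i - 1L) %% length(SYN_FIRST_NAMES) + 1L]
  ln <- SYN_LAST_NAMES[(i * 7L) %% length(SYN_LAST_NAMES) + 1L]
  switch(family,
    email = paste0(tolower(fn), ".", tolower(ln), "@example.com"),
    phone = sprintf("%03d-%03d-%04d", 200 + (i * 13L) %% 700,
                    100 + (i * 31L) %% 900, (i * 97L) %% 10000),
    `ssn-like` = sprintf("%03d-%02d-%04d", 100 + (i * 17L) %% 800,
                         10 + (i * 5L) %% 89, (i * 41L) %% 10000),
    `date-like` = format(as.Date("2019-01-01") + (i * 37L) %% 730, "%Y-%m-%d"),
    `name-like` = paste("seen by Dr.", ln),
    stop("unknown plant family: ", family, call. = FALSE))
}

default_gen_options <- function() {
  list(phi_rate = 0.2,
       phi_families = c("email", "phone", "ssn-like", "name-like"),
       rare_events = NULL,
       death_fraction = 0.05,
       pre_reference_fraction = 0,
       partial_date_fraction = 0,
       direct_columns = TRUE,
       enrolment_start = "2019-06-01",
       enrolment_days = 180)
}

#' Generate a synthetic multi-domain clinical trial
#'
#' Emits a study with DM (demographics: subject and site codes, country,
#' planted name/email/phone/SSN-like/ZIP columns, date of birth, sex, race,
#' ethnicity, height, weight, arm, first-dose reference date), AE (verbatim
#' adverse-event text with identifier-like strings planted at
#' `options$phi_rate`, dictionary-coded term, start/end dates), VS and LB
#' (visit dates and measurements on a fixed visit grid with jitter) and DS
#' (disposition, with death dates for `options$death_fraction` of
#' subjects), together with a ground-truth manifest. Deterministic given
#' the seed.
#'
#' Ages are drawn uniformly on 18–95 so the over-89 top-coding boundary is
#' exercised; `options$pre_reference_fraction` moves that share of AE start
#' dates before the reference date to exercise negative study days;
#' `options$partial_date_fraction` truncates that share of AE end dates to
#' `YYYY-MM` to exercise the partial-date policy.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_sites Number of sites (>= 1; truncated with a warning when it
#'   exceeds `n_subjects`).
#' @param seed Integer seed.
#' @param options Named list overriding any of the defaults above;
#'   `options$rare_events` is a named list of coded terms to exact
#'   distinct-subject counts (e.g. `list("Stevens-Johnson syndrome" = 2)`).
#' @return `list(study =, truth =)`; `truth` has `planted` (table,
#'   variable, record, family, value), `covariates` (per-subject age, sex,
#'   race, site, country, arm), `reference_dates`, and `rare_events`.
#' @export
generate_study <- function(n_subjects, n_sites, seed, options = list()) {
  stopifnot(n_subjects >= 1, n_sites >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_sites > n_subjects) {
    warning("n_sites > n_subjects; truncating to ", n_subjects, call. = FALSE)
    n_sites <- n_subjects
  }
  opt <- utils::modifyList(default_gen_options(), options)
  withr::with_seed(seed, generate_study_impl(n_subjects, n_sites, opt))
}

generate_study_impl <- function(n, n_sites, opt) {
  subjid <- sprintf("P%04d", seq_len(n))
  siteid <- as.character(1000 + sample.int(n_sites, n, replace = TRUE))
  site_country <- stats::setNames(
    SYN_COUNTRIES[(seq_len(n_sites) - 1L) %% length(SYN_COUNTRIES) + 1L],
    as.character(1000 + seq_len(n_sites)))
  country <- unname(site_country[siteid])
  age <- sample(18:95, n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  race <- sample(SYN_RACES, n, replace = TRUE,
                 prob = c(30, 15, 15, 8, 5, 4, 10, 2, 2) / 91)
  ethnic <- sample(SYN_ETHNICITIES, n, replace = TRUE)
  height <- sprintf("%.1f", stats::runif(n, 150, 195))
  weight <- sprintf("%.1f", stats::runif(n, 45, 120))
  arm <- sample(c("PLACEBO", "ACTIVE"), n, replace = TRUE)
  ref <- as.Date(opt$enrolment_start) +
    sample.int(opt$enrolment_days, n, replace = TRUE) - 1L
  dob <- dob_for_age(age, ref)
  fn <- sample(SYN_FIRST_NAMES, n, replace = TRUE)
  ln <- sample(SYN_LAST_NAMES, n, replace = TRUE)

  dm <- data.frame(
    SUBJID = subjid, SITEID = siteid, COUNTRY = country,
    BRTHDTC = format(dob, "%Y-%m-%d"), SEX = sex, RACE = race,
    ETHNIC = ethnic, HEIGHT = height, WEIGHT = weight, ARM = arm,
    RFSTDTC = format(ref, "%Y-%m-%d"))
  if (isTRUE(opt$direct_columns)) {
    dm$NAME <- paste(fn, ln)
    dm$EMAIL <- paste0(tolower(fn), ".", tolower(ln), "@example.com")
    dm$PHONE <- sprintf("%03d-%03d-%04d", sample(200:899, n, TRUE),
                        sample(100:999, n, TRUE), sample(0:9999, n, TRUE))
    dm$SSN <- sprintf("%03d-%02d-%04d", sample(100:899, n, TRUE),
                      sample(10:99, n, TRUE), sample(0:9999, n, TRUE))
    dm$ZIP <- sprintf("%05d", sample(1000:99999, n, TRUE))
  }

  # adverse events: 0-3 per subject, plus exact-count rare events
  n_ae <- sample(0:3, n, replace = TRUE)
  ae_rows <- list()
  planted <- list()
  for (i in seq_len(n)) {
    if (n_ae[i] == 0L) next
    pick <- sample.int(nrow(SYN_AE_TERMS), n_ae[i], replace = TRUE)
    st <- ref[i] + sample.int(120, n_ae[i], replace = TRUE)
    if (opt$pre_reference_fraction > 0) {
      flip <- stats::runif(n_ae[i]) < opt$pre_reference_fraction
      st[flip] <- ref[i] - sample.int(60, sum(flip), replace = TRUE)
    }
    en <- st + sample.int(14, n_ae[i], replace = TRUE) - 1L
    ae_rows[[i]] <- data.frame(
      SUBJID = subjid[i],
      AETERM = SYN_AE_TERMS$verbatim[pick],
      AEDECOD = SYN_AE_TERMS$decod[pick],
      AESTDTC = format(st, "%Y-%m-%d"),
      AEENDTC = format(en, "%Y-%m-%d"))
  }
  ae <- if (length(ae_rows)) do.call(rbind, ae_rows) else
    data.frame(SUBJID = character(), AETERM = character(),
               AEDECOD = character(), AESTDTC = character(),
               AEENDTC = character())
  rare_plan <- list()
  for (term in names(opt$rare_events)) {
    k <- opt$rare_events[[term]]
    if (k > n) stop("rare event count exceeds number of subjects", call. = FALSE)
    carriers <- sample(subjid, k)
    st <- ref[match(carriers, subjid)] + sample.int(90, k, replace = TRUE)
    ae <- rbind(ae, data.frame(
      SUBJID = carriers,
      AETERM = paste("serious reaction consistent with",tolower(term)),
      AEDECOD = term,
      AESTDTC = format(st, "%Y-%m-%d"),
      AEENDTC = format(st + 7L, "%Y-%m-%d")))
    rare_plan[[term]] <- k
  }
  if (nrow(ae)) {
    ae <- ae[order(ae$SUBJID, ae$AESTDTC), , drop = FALSE]
    rownames(ae) <- NULL
  }
  if (opt$partial_date_fraction > 0 && nrow(ae)) {
    cut <- which(stats::runif(nrow(ae)) < opt$partial_date_fraction)
    ae$AEENDTC[cut] <- substr(ae$AEENDTC[cut], 1, 7)
  }
  # plant identifier-like strings into the verbatim text
  if (opt$phi_rate > 0 && nrow(ae)) {
    hit <- which(stats::runif(nrow(ae)) < opt$phi_rate)
    fams <- sample(opt$phi_families, length(hit), replace = TRUE)
    for (j in seq_along(hit)) {
      val <- syn_phi_value(fams[j], sample.int(10000, 1))
      ae$AETERM[hit[j]] <- paste(ae$AETERM[hit[j]], val)
      planted[[length(planted) + 1L]] <- data.frame(
        table = "AE", variable = "AETERM", record = hit[j],
        family = fams[j], value = val)
    }
  }

  # vitals and labs on a fixed visit grid with small jitter
  grid <- c(1L, 29L, 57L, 85L)
  vs_rows <- list(); lb_rows <- list()
  for (i in seq_len(n)) {
    vd <- ref[i] + grid - 1L + sample(-3:3, length(grid), replace = TRUE)
    vd[1] <- ref[i]
    vs_rows[[i]] <- data.frame(
      SUBJID = subjid[i], VISITNUM = as.character(seq_along(grid)),
      VSDTC = format(vd, "%Y-%m-%d"),
      VSTESTCD = "SYSBP",
      VSORRES = sprintf("%.0f", stats::rnorm(length(grid), 125, 12)))
    lb_rows[[i]] <- data.frame(
      SUBJID = subjid[i], VISITNUM = as.character(seq_along(grid)),
      LBDTC = format(vd, "%Y-%m-%d"),
      LBTESTCD = "ALT",
      LBORRES = sprintf("%.1f", stats::rlnorm(length(grid), log(25), 0.4)))
  }
  vs <- do.call(rbind, vs_rows)
  lb <- do.call(rbind, lb_rows)

  died <- stats::runif(n) < opt$death_fraction
  ds <- data.frame(
    SUBJID = subjid,
    DSDECOD = ifelse(died, "DEATH", "COMPLETED"),
    DSSTDTC = format(ref + sample(90:180, n, replace = TRUE), "%Y-%m-%d"))

  kinds <- list(
    DM = c(BRTHDTC = "calendar-date", RFSTDTC = "calendar-date",
           HEIGHT = "decimal", WEIGHT = "decimal"),
    AE = c(AESTDTC = "calendar-date",
           AEENDTC = if (opt$partial_date_fraction > 0) "partial-date"
                     else "calendar-date"),
    VS = c(VSDTC = "calendar-date", VSORRES = "decimal"),
    LB = c(LBDTC = "calendar-date", LBORRES = "decimal"),
    DS = c(DSSTDTC = "calendar-date"))

  study <- new_study(
    list(DM = dm, AE = ae, VS = vs, LB = lb, DS = ds),
    subject_key = "SUBJID", site_key = "SITEID", kinds = kinds,
    subject_level_table = "DM",
    reference_date = list(mode = "per-subject", table = "DM",
                          variable = "RFSTDTC"),
    provenance = list(generator = "trialdeid::generate_study"))

  truth <- list(
    planted = if (length(planted)) do.call(rbind, planted) else
      data.frame(table = character(), variable = character(),
                 record = integer(), family = character(),
                 value = character()),
    covariates = data.frame(SUBJID = subjid, AGE = age, SEX = sex,
                            RACE = race, SITEID = siteid, COUNTRY = country,
                            ARM = arm),
    reference_dates = stats::setNames(format(ref, "%Y-%m-%d"), subjid),
    rare_events = rare_plan)
  list(study = study, truth = truth)
}

# date of birth exactly `age` completed years before `ref`: the birthday
# in ref's year is moved earlier by 0..330 days, which cannot cross the
# next anniversary
dob_for_age <- function(age, ref) {
  lt <- as.POSIXlt(ref)
  lt$year <- lt$year - age
  bad <- lt$mon == 1L & lt$mday == 29L  # Feb 29 in a possibly non-leap year
  lt$mday[bad] <- 28L
  anchor <- as.Date(lt)
  anchor - sample(0:330, length(age), replace = TRUE)
}

#' Plant identifier-like strings into free-text cells
#'
#' Appends pattern-family strings (emails, phone numbers, SSN-like codes,
#' ISO dates, names from the built-in word list) to free-text cells at the
#' given rate and returns the exact coordinates, extending a ground-truth
#' manifest.
#'
#' @param study A `trial_study` containing the target free-text variable.
#' @param rate Planting probability per cell, in `[0, 1]`.
#' @param families Plant families (subset of `email`, `phone`, `ssn-like`,
#'   `date-like`, `name-like`).
#' @param seed Integer seed.
#' @param table,variable Target free-text cell column (default
#'   `AE.AETERM`).
#' @return `list(study =, planted =)` where `planted` is the manifest delta
#'   (table, variable, record, family, value).
#' @export
inject_identifiers <- function(study, rate, families = c("email", "phone"),
                               seed, table = "AE", variable = "AETERM") {
  stopifnot(rate >= 0, rate <= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  tab <- study$tables[[table]]
  if (is.null(tab) || !variable %in% names(tab))
    stop("no free-text variable ", table, ".", variable, " present",
         call. = FALSE)
  empty <- data.frame(table = character(), variable = character(),
                      record = integer(), family = character(),
                      value = character())
  if (nrow(tab) == 0L || rate == 0)
    return(list(study = study, planted = empty))
  res <- withr::with_seed(seed, {
    hit <- which(stats::runif(nrow(tab)) < rate)
    fams <- if (length(hit)) sample(families, length(hit), replace = TRUE)
            else character(0)
    vals <- vapply(seq_along(hit),
                   function(j) syn_phi_value(fams[j], sample.int(10000, 1)),
                   character(1))
    list(hit = hit, fams = fams, vals = vals)
  })
  if (!length(res$hit)) return(list(study = study, planted = empty))
  x <- tab[[variable]]
  x[res$hit] <- paste(ifelse(is.na(x[res$hit]), "", x[res$hit]), res$vals)
  x[res$hit] <- trimws(x[res$hit])
  study$tables[[table]][[variable]] <- x
  list(study = study,
       planted = data.frame(table = table, variable = variable,
                            record = res$hit, family = res$fams,
                            value = res$vals))
}
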