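# Date de-identification: study days (SDTM --DY convention: day 1 is the
# reference date, there is no day 0), per-subject offset dates, age at
# reference in place of date of birth, and optional month/season retention.

#' Study day relative to a reference date
#'
#' SDTM day-numbering convention: the reference date is day 1 and there is
#' no day 0, so a date on or after the reference maps to
#' `(date - reference) + 1` and an earlier date to `date - reference`
#' (negative).
#'
#' @param date,reference `Date` vectors or ISO `YYYY-MM-DD` strings
#'   (recycled). Partial dates are a hard error here; route them through the
#'   partial-date policy first.
#' @return Signed integer vector; never 0. `NA` where either input is `NA`.
#' @export
study_day <- function(date, reference) {
  if (any(is_partial_date(date)) || any(is_partial_date(reference)))
    stop("partial date passed to study_day(); apply the partial-date policy first",
         call. = FALSE)
  d <- if (inherits(date, "Date")) date else parse_iso_date(date)
  r <- if (inherits(reference, "Date")) reference else parse_iso_date(reference)
  diff <- as.integer(d - r)
  ifelse(diff >= 0L, diff + 1L, diff)
}

#' Age in completed years at a reference date
#'
#' Replaces date of birth with the subject's age: the number of birthdays
#' reached on or before the reference date. A Feb 29 birthday is deemed
#' reached on Feb 28 of non-leap years.
#'
#' @param dob,reference `Date` vectors or ISO strings (recycled);
#'   `dob <= reference` required.
#' @return Integer vector of completed years; `NA` propagates.
#' @export
derive_age <- function(dob, reference) {
  d <- if (inherits(dob, "Date")) dob else parse_iso_date(dob)
  r <- if (inherits(reference, "Date")) reference else parse_iso_date(reference)
  n <- max(length(d), length(r))
  d <- rep_len(d, n); r <- rep_len(r, n)
  ok <- !is.na(d) & !is.na(r)
  if (any(d[ok] > r[ok]))
    stop("date of birth after reference date", call. = FALSE)
  dl <- as.POSIXlt(d); rl <- as.POSIXlt(r)
  by <- dl$year; bm <- dl$mon; bd <- dl$mday
  ry <- rl$year; rm <- rl$mon; rd <- rl$mday
  # anniversary day in the reference year; Feb 29 -> Feb 28 when not leap
  leap <- function(y) { y <- y + 1900; (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0 }
  ad <- ifelse(bm == 1L & bd == 29L & !leap(ry), 28L, bd)
  reached <- (rm > bm) | (rm == bm & rd >= ad)
  age <- ry - by - ifelse(reached, 0L, 1L)
  age[!ok] <- NA_integer_
  as.integer(age)
}

# Resolve the per-subject reference date map from a reference-date spec.
# spec: list(mode = "per-subject", table =, variable =, fallback =) or
#       list(mode = "trial-level", date = "YYYY-MM-DD")
reference_dates <- function(study, ref) {
  subjects <- study$tables[[study$subject_level_table]][[study$subject_key]]
  mode <- ref$mode %||% "per-subject"
  if (mode == "trial-level") {
    rd <- parse_iso_date(ref$date)
    if (is.na(rd)) stop("trial-level reference date is not a valid ISO date",
                        call. = FALSE)
    return(stats::setNames(rep(rd, length(subjects)), subjects))
  }
  tab <- study$tables[[ref$table]]
  if (is.null(tab) || !ref$variable %in% names(tab))
    stop("reference date variable ", ref$table, ".", ref$variable,
         " not found", call. = FALSE)
  idx <- match(subjects, tab[[study$subject_key]])
  rd <- parse_iso_date(tab[[ref$variable]][idx])
  stats::setNames(rd, subjects)
}

# Apply the declared partial-date imputation policy to a character vector.
# Returns list(dates = Date vector, imputed = idx, dropped = idx).
impute_partial <- function(x, policy = c("none", "month-midpoint",
                                         "conservative-drop")) {
  policy <- match.arg(policy)
  part <- which(is_partial_date(x))
  dates <- parse_iso_date(x)
  imputed <- integer(0); dropped <- integer(0)
  if (length(part)) {
    if (policy == "none")
      stop(length(part), " partial date(s) present and partial policy is ",
           "'none'; declare month-midpoint or conservative-drop", call. = FALSE)
    if (policy == "month-midpoint") {
      ym <- grepl("^\\d{4}-\\d{2}$", x[part])
      full <- ifelse(ym, paste0(x[part], "-15"), paste0(x[part], "-07-01"))
      dates[part] <- as.Date(full)
      imputed <- part
    } else {
      dropped <- part
    }
  }
  list(dates = dates, imputed = imputed, dropped = dropped)
}

# Variables subject to the date rule: kind calendar-date (or partial-date)
# whose classification does not say keep, excluding the reference variable
# itself when asked, and excluding date-of-birth (handled by derive_age).
date_rule_targets <- function(study, classification, exclude = character()) {
  out <- list()
  for (dom in names(study$tables)) {
    k <- study$kinds[[dom]]
    for (v in names(k)[k %in% c("calendar-date", "partial-date")]) {
      meta <- classification[[v]]
      if (!is.null(meta) &&
          (meta$retain_policy == "keep" || meta$role == "date-of-birth")) next
      if (v %in% exclude) next
      out[[length(out) + 1L]] <- c(table = dom, variable = v)
    }
  }
  out
}

dy_name <- function(v) {
  if (grepl("DTC$", v)) sub("DTC$", "DY", v) else paste0(v, "_DY")
}

#' Replace calendar dates with study days across a study
#'
#' Every calendar-date variable not flagged keep (and not a date of birth,
#' which [derive_age()] handles) is replaced by an integer study-day
#' variable named by the SDTM suffix rule (`AESTDTC` becomes `AESTDY`;
#' other names gain `_DY`). Original date values are absent from the
#' output. Partial dates follow `partial_policy`; subjects lacking a
#' reference date follow `ref$fallback` (`"error"` or
#' `"drop-subject-dates"`).
#'
#' @param study A `trial_study`.
#' @param ref Reference-date spec: `list(mode = "per-subject", table =,
#'   variable =, fallback = "error")` or `list(mode = "trial-level",
#'   date =)`.
#' @param classification Output of [classify_variables()].
#' @param partial_policy `"none"`, `"month-midpoint"` or
#'   `"conservative-drop"`.
#' @return `list(study =, log =)` where `log` is a data frame of actions
#'   (one row per transformed variable, plus imputation/drop counts).
#' @export
apply_study_days <- function(study, ref, classification,
                             partial_policy = "none") {
  refmap <- reference_dates(study, ref)
  fallback <- ref$fallback %||% "error"
  if (anyNA(refmap)) {
    if (fallback == "error")
      stop("subject(s) lacking a reference date: ",
           paste(utils::head(names(refmap)[is.na(refmap)], 5), collapse = ", "),
           call. = FALSE)
  }
  exclude <- if ((ref$mode %||% "per-subject") == "per-subject")
    ref$variable else character(0)
  targets <- date_rule_targets(study, classification, exclude = exclude)
  log <- empty_log()
  for (tv in targets) {
    dom <- tv[["table"]]; v <- tv[["variable"]]
    tab <- study$tables[[dom]]
    imp <- impute_partial(tab[[v]], partial_policy)
    subj <- tab[[study$subject_key]]
    rd <- refmap[subj]
    dy <- study_day(imp$dates, rd)
    dy[is.na(rd)] <- NA_integer_  # drop-subject-dates fallback
    newv <- dy_name(v)
    tab[[v]] <- as.character(dy)
    names(tab)[names(tab) == v] <- newv
    study$tables[[dom]] <- tab
    study$kinds[[dom]] <- stats::setNames(
      ifelse(names(study$kinds[[dom]]) == v, "integer", study$kinds[[dom]]),
      replace(names(study$kinds[[dom]]), names(study$kinds[[dom]]) == v, newv))
    log <- log_append(log, dom, v, "dates.study_day", "transformed",
                      sprintf("replaced by %s; %d imputed, %d dropped, %d no-reference",
                              newv, length(imp$imputed), length(imp$dropped),
                              sum(is.na(rd))),
                      n = length(dy))
    log <- log_append(log, dom, newv, "dates.study_day", "added",
                      paste0("study day derived from ", v), n = length(dy))
  }
  # the reference variable itself is a patient date: drop it from output
  if (length(exclude)) {
    dom <- ref$table
    if (exclude %in% names(study$tables[[dom]])) {
      study$tables[[dom]][[exclude]] <- NULL
      study$kinds[[dom]] <-
        study$kinds[[dom]][names(study$kinds[[dom]]) != exclude]
      log <- log_append(log, dom, exclude, "dates.reference_removed",
                        "removed", "reference date variable removed after use",
                        n = 1L)
    }
  }
  list(study = study, log = log)
}

#' Shift all of each subject's dates by one random offset
#'
#' Draws one signed day offset per subject, uniformly from `bounds`
#' (excluding zero by default, so no subject keeps true dates), and shifts
#' every calendar date of that subject by it — preserving all within-subject
#' intervals exactly. With `constrain_to_trial_range`, each subject's offset
#' is drawn from the subset of offsets that keep all their shifted dates
#' inside the original trial-wide date range; when no such offset exists the
#' subject's dates are blanked and the subject is recorded as a fallback
#' (with a warning) for the study-day method.
#'
#' @param study A `trial_study`.
#' @param seed Integer seed.
#' @param bounds `c(lo, hi)` in days, `lo <= hi`.
#' @param constrain_to_trial_range Keep shifted dates within the original
#'   trial date range (default `TRUE`).
#' @param exclude_zero Disallow a zero offset (default `TRUE`).
#' @param classification Output of [classify_variables()] (controls which
#'   variables are date-rule targets).
#' @param partial_policy Partial-date policy, as in [apply_study_days()].
#' @return `list(study =, plan =, log =)`; `plan` is an `offset_plan` with
#'   per-subject offsets, bounds, the seed fingerprint and any fallback
#'   subjects.
#' @export
offset_dates <- function(study, seed, bounds, constrain_to_trial_range = TRUE,
                         exclude_zero = TRUE, classification,
                         partial_policy = "none") {
  stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  targets <- date_rule_targets(study, classification)
  # parse all target dates once; collect trial range and per-subject spans
  parsed <- list(); log <- empty_log()
  all_dates <- as.Date(character(0))
  for (i in seq_along(targets)) {
    tv <- targets[[i]]
    imp <- impute_partial(study$tables[[tv[["table"]]]][[tv[["variable"]]]],
                          partial_policy)
    parsed[[i]] <- imp
    all_dates <- c(all_dates, imp$dates[!is.na(imp$dates)])
  }
  if (!length(all_dates))
    stop("study contains no parseable calendar dates to offset", call. = FALSE)
  trial_min <- min(all_dates); trial_max <- max(all_dates)
  subjects <- study$tables[[study$subject_level_table]][[study$subject_key]]
  span_min <- stats::setNames(rep(as.Date(NA), length(subjects)), subjects)
  span_max <- span_min
  for (i in seq_along(targets)) {
    tv <- targets[[i]]
    subj <- study$tables[[tv[["table"]]]][[study$subject_key]]
    d <- parsed[[i]]$dates
    for (j in which(!is.na(d))) {
      s <- subj[j]
      if (is.na(span_min[s]) || d[j] < span_min[s]) span_min[s] <- d[j]
      if (is.na(span_max[s]) || d[j] > span_max[s]) span_max[s] <- d[j]
    }
  }
  candidates <- seq.int(bounds[1], bounds[2])
  if (exclude_zero) candidates <- candidates[candidates != 0L]
  if (!length(candidates))
    stop("offset bounds leave no candidate offsets", call. = FALSE)
  offsets <- withr::with_seed(seed, {
    vapply(subjects, function(s) {
      feas <- candidates
      if (constrain_to_trial_range && !is.na(span_min[s])) {
        lo <- as.integer(trial_min - span_min[s])
        hi <- as.integer(trial_max - span_max[s])
        feas <- feas[feas >= lo & feas <= hi]
      }
      if (!length(feas)) return(NA_integer_)
      feas[sample.int(length(feas), 1L)]
    }, integer(1))
  })
  fallback <- names(offsets)[is.na(offsets)]
  if (length(fallback))
    warning(length(fallback), " subject(s) had no feasible in-range offset; ",
            "their dates were blanked and logged for the study-day fallback",
            call. = FALSE)
  for (i in seq_along(targets)) {
    tv <- targets[[i]]
    dom <- tv[["table"]]; v <- tv[["variable"]]
    subj <- study$tables[[dom]][[study$subject_key]]
    d <- parsed[[i]]$dates
    shifted <- d + offsets[subj]
    out <- ifelse(is.na(shifted), NA_character_, format(shifted, "%Y-%m-%d"))
    study$tables[[dom]][[v]] <- out
    study$kinds[[dom]][[v]] <- "calendar-date"
    log <- log_append(log, dom, v, "dates.offset", "transformed",
                      sprintf("per-subject offset in [%d,%d]%s; %d imputed, %d dropped",
                              bounds[1], bounds[2],
                              if (exclude_zero) " excluding 0" else "",
                              length(parsed[[i]]$imputed),
                              length(parsed[[i]]$dropped)),
                      n = sum(!is.na(out)))
  }
  plan <- structure(
    list(offsets = offsets[!is.na(offsets)],
         bounds = bounds,
         exclude_zero = exclude_zero,
         constrain_to_trial_range = constrain_to_trial_range,
         trial_range = c(trial_min, trial_max),
         fallback_subjects = fallback,
         seed_fingerprint = fingerprint(c("seed", seed))),
    class = "offset_plan")
  if (length(fallback))
    log <- log_append(log, "(all)", study$subject_key, "dates.offset_fallback",
                      "blanked",
                      paste("no feasible in-range offset for:",
                            paste(fallback, collapse = ", ")),
                      n = length(fallback))
  list(study = study, plan = plan, log = log)
}

#' Derive and retain month or season from a date variable
#'
#' Adds a categorical companion variable before the raw date is transformed
#' away, for analyses of seasonal disease where calendar timing carries
#' scientific value: month 1–12 or meteorological season (DJF, MAM, JJA,
#' SON). Works for partial `YYYY-MM` dates, whose month is recoverable.
#'
#' @param study A `trial_study`.
#' @param variable A calendar-date (or partial-date) variable present in the
#'   study.
#' @param granularity `"month"` or `"season"`.
#' @return `list(study =, log =)`; the new variable is `<variable>_MONTH`
#'   or `<variable>_SEASON`.
#' @export
retain_season <- function(study, variable, granularity = c("month", "season")) {
  granularity <- match.arg(granularity)
  dom <- NULL
  for (d in names(study$tables))
    if (variable %in% names(study$tables[[d]])) { dom <- d; break }
  if (is.null(dom))
    stop("variable '", variable, "' not found in any table", call. = FALSE)
  kind <- study$kinds[[dom]][[variable]]
  if (!kind %in% c("calendar-date", "partial-date"))
    stop("variable '", variable, "' is not a date variable", call. = FALSE)
  x <- study$tables[[dom]][[variable]]
  month <- suppressWarnings(
    as.integer(ifelse(grepl("^\\d{4}-\\d{2}", x), substr(x, 6, 7), NA)))
  month[!is.na(month) & (month < 1L | month > 12L)] <- NA_integer_
  newv <- paste0(variable, "_", toupper(granularity))
  val <- if (granularity == "month") as.character(month)
  else c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
         "SON", "SON", "SON", "DJF")[month]
  study$tables[[dom]][[newv]] <- val
  study$kinds[[dom]][[newv]] <- if (granularity == "month") "integer" else "text"
  log <- log_append(empty_log(), dom, newv, "dates.retain_season", "added",
                    paste0("derived from ", variable), n = sum(!is.na(val)))
  list(study = study, log = log)
}
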