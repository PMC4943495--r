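# Orchestration of the full best-practice sequence behind a single config:
# classify -> remove direct identifiers -> recode subjects/sites -> date
# transforms -> generalisation -> free-text scrub -> subset -> risk -> report,
# with the quality-control step run automatically at the end. Stage order is
# fixed: risk must be computed on the data as shared, and re-coding precedes
# the date transforms so the log references the shared codes consistently.

#' Run the de-identification pipeline
#'
#' Applies every configured rule in a fixed, documented order and returns
#' the de-identified study with its transformation log, risk report, code
#' keys, QC findings and rendered report. The configuration must state the
#' code-key disposition (`"store"` or `"destroy"`) and the subset selection
#' (`"all"` or an explicit table/variable selection) explicitly — neither
#' has a silent default, because both are accountability decisions.
#'
#' @param study A `trial_study`, or `NULL` to read from
#'   `config$input$paths` with `config$input$layout`.
#' @param config Pipeline configuration list, or a path to a YAML/JSON
#'   file. See the package vignette for the full schema.
#' @return `list(study =, log =, risk =, keys =, qc =, report =, review =,
#'   classification =)`. `qc_passed(result$qc)` tells whether the run may
#'   ship.
#' @export
run_deidentify <- function(study = NULL, config) {
  config <- load_config(config)
  if (is.null(study)) {
    if (is.null(config$input))
      stop("no study given and config has no input section", call. = FALSE)
    study <- read_study(config$input$paths, config$input$layout)
  }
  if (is.null(config$keys$disposition) ||
      !config$keys$disposition %in% c("store", "destroy"))
    stop("config$keys$disposition must be 'store' or 'destroy' (no default)",
         call. = FALSE)
  if (is.null(config$subset))
    stop("config$subset must be declared: \"all\" or a table/variable ",
         "selection (no default; sharing everything is a decision)",
         call. = FALSE)
  timestamp <- config$report$timestamp %||% ""
  original <- study
  log <- empty_log()
  fingerprints <- character(0)
  review <- NULL

  # 1. classification -------------------------------------------------------
  classification <- classify_variables(study, config$classification %||% list())
  needs_review <- attr(classification, "needs_review")

  # 2. removal of variables whose policy is remove (verbatim text is handled
  #    by the scrub stage so coded counterparts are enforced) ----------------
  for (dom in names(study$tables)) {
    for (v in names(study$tables[[dom]])) {
      meta <- classification[[v]]
      if (is.null(meta) || meta$role == "verbatim-text") next
      if (meta$retain_policy %in% c("remove", "blank")) {
        n <- sum(!is.na(study$tables[[dom]][[v]]))
        if (meta$retain_policy == "remove") {
          study$tables[[dom]][[v]] <- NULL
          study$kinds[[dom]] <-
            study$kinds[[dom]][names(study$kinds[[dom]]) != v]
          log <- log_append(log, dom, v, "direct.remove", "removed",
                            paste0("registry code ",
                                   meta$registry_code %||% "(none)"), n = n)
        } else {
          study$tables[[dom]][[v]][] <- NA_character_
          log <- log_append(log, dom, v, "direct.blank", "blanked",
                            "values set to missing", n = n)
        }
      }
    }
  }

  # 3. subject / site re-coding --------------------------------------------
  seed <- config$keys$seed
  if (is.null(seed)) stop("config$keys$seed is required", call. = FALSE)
  keys <- list()
  rs <- remap_subjects(study, seed = seed,
                       template = config$keys$subject_template %||% "S#####",
                       prior_key = config$keys$prior_subject_key)
  study <- rs$study; keys$subject <- rs$key
  fingerprints["subject_key_seed"] <- rs$key$seed_fingerprint
  for (dom in names(study$tables))
    log <- log_append(log, dom, study$subject_key, "pseudonym.subject",
                      "recoded", "random injection, content-independent",
                      n = nrow(study$tables[[dom]]))
  if (!is.null(study$site_key) && isTRUE(config$keys$recode_sites %||% TRUE)) {
    rsit <- remap_sites(study, seed = seed + 1L,
                        template = config$keys$site_template %||% "T###",
                        prior_key = config$keys$prior_site_key)
    study <- rsit$study; keys$site <- rsit$key
    fingerprints["site_key_seed"] <- rsit$key$seed_fingerprint
    for (dom in names(study$tables))
      if (study$site_key %in% names(study$tables[[dom]]))
        log <- log_append(log, dom, study$site_key, "pseudonym.site",
                          "recoded", "random injection",
                          n = nrow(study$tables[[dom]]))
  }

  # 4. dates ----------------------------------------------------------------
  dcfg <- config$dates %||% list()
  ref <- dcfg$reference %||% study$reference_date
  if (is.null(ref))
    stop("no reference-date specification (config$dates$reference or the ",
         "study's reference_date)", call. = FALSE)
  partial_policy <- dcfg$partial_policy %||% "none"
  for (rs_ in dcfg$retain_season %||% list()) {
    r <- retain_season(study, rs_$variable, rs_$granularity %||% "month")
    study <- r$study; log <- rbind(log, r$log)
  }
  refmap <- reference_dates(study, ref)
  for (dom in names(study$tables)) {
    for (v in names(study$tables[[dom]])) {
      meta <- classification[[v]]
      if (is.null(meta) || meta$role != "date-of-birth") next
      tab <- study$tables[[dom]]
      # refmap was built after re-coding, so it is keyed by the new codes
      subj <- tab[[study$subject_key]]
      age <- derive_age(tab[[v]], refmap[subj])
      agevar <- dcfg$age_variable %||% "AGE"
      tab[[agevar]] <- as.character(age)
      tab[[v]] <- NULL
      study$tables[[dom]] <- tab
      study$kinds[[dom]] <-
        study$kinds[[dom]][names(study$kinds[[dom]]) != v]
      study$kinds[[dom]][[agevar]] <- "integer"
      log <- log_append(log, dom, v, "dates.dob_to_age", "removed",
                        paste0("replaced by ", agevar,
                               " (completed years at reference)"),
                        n = sum(!is.na(age)))
      log <- log_append(log, dom, agevar, "dates.dob_to_age", "added",
                        paste0("age derived from ", v), n = sum(!is.na(age)))
    }
  }
  method <- dcfg$method %||% "study_day"
  if (method == "study_day") {
    sd <- apply_study_days(study, ref, classification,
                           partial_policy = partial_policy)
    study <- sd$study; log <- rbind(log, sd$log)
  } else if (method == "offset") {
    ocfg <- dcfg$offset %||% list()
    od <- offset_dates(study, seed = seed + 2L,
                       bounds = c(ocfg$lo %||% -30L, ocfg$hi %||% 30L),
                       constrain_to_trial_range =
                         ocfg$constrain_to_trial_range %||% TRUE,
                       exclude_zero = ocfg$exclude_zero %||% TRUE,
                       classification = classification,
                       partial_policy = partial_policy)
    study <- od$study; log <- rbind(log, od$log)
    fingerprints["offset_seed"] <- od$plan$seed_fingerprint
    keys$offset_plan <- od$plan
  } else stop("unknown date method '", method, "'", call. = FALSE)

  # 5. generalisation --------------------------------------------------------
  gcfg <- config$generalise %||% list()
  acfg <- gcfg$age
  if (!is.null(acfg)) {
    agevar <- acfg$variable %||% "AGE"
    for (dom in names(study$tables)) {
      if (!agevar %in% names(study$tables[[dom]])) next
      x <- cap_age(study$tables[[dom]][[agevar]],
                   cap = acfg$cap %||% 89, label = acfg$label %||% ">89")
      lab <- acfg$label %||% ">89"
      capped <- !is.na(x) & x == lab
      n_cap <- sum(capped)
      if (!is.null(acfg$bin_width)) {
        spec <- bin_spec(acfg$bin_width, style = "integer")
        x <- as.character(bin_value(x, spec))
        x[capped] <- lab  # the top category is already coarser than any bin
      }
      study$tables[[dom]][[agevar]] <- x
      study$kinds[[dom]][[agevar]] <- "text"
      log <- log_append(log, dom, agevar, "generalise.age", "transformed",
                        sprintf("top-coded above %d as '%s'%s (%d capped)",
                                acfg$cap %||% 89, acfg$label %||% ">89",
                                if (!is.null(acfg$bin_width))
                                  paste0("; binned width ", acfg$bin_width)
                                else "", n_cap),
                        n = sum(!is.na(x)))
    }
  }
  if (!is.null(gcfg$race)) {
    rvar <- gcfg$race$variable %||% "RACE"
    mapping <- if (!is.null(gcfg$race$map)) gcfg$race$map else default_race_map()
    for (dom in names(study$tables)) {
      if (!rvar %in% names(study$tables[[dom]])) next
      mapped <- map_race(study$tables[[dom]][[rvar]], mapping)
      unmapped <- attr(mapped, "unmapped")
      study$tables[[dom]][[rvar]] <- as.character(mapped)
      log <- log_append(log, dom, rvar, "generalise.race", "transformed",
                        paste0("mapped to FDA categories",
                               if (length(unmapped))
                                 paste0("; unmapped -> review: ",
                                        paste(unmapped, collapse = ", "))
                               else ""),
                        n = sum(!is.na(mapped)))
      if (length(unmapped))
        review <- c(review, paste0("unmapped race value(s) in ", dom, ".",
                                   rvar, ": ",
                                   paste(unmapped, collapse = ", ")))
    }
  }
  ecfg <- gcfg$ethnicity
  if (!is.null(ecfg) && isTRUE(ecfg$remove %||% TRUE)) {
    evar <- ecfg$variable %||% "ETHNIC"
    for (dom in names(study$tables)) {
      if (!evar %in% names(study$tables[[dom]])) next
      n <- sum(!is.na(study$tables[[dom]][[evar]]))
      study$tables[[dom]][[evar]] <- NULL
      study$kinds[[dom]] <-
        study$kinds[[dom]][names(study$kinds[[dom]]) != evar]
      log <- log_append(log, dom, evar, "generalise.ethnicity", "removed",
                        "ethnicity removed", n = n)
    }
  }
  for (prule in gcfg$pooling %||% list()) {
    pvar <- prule$variable
    for (dom in names(study$tables)) {
      if (!pvar %in% names(study$tables[[dom]])) next
      pr <- pool_rare_categories(study$tables[[dom]], pvar,
                                 study$subject_key,
                                 min_count = prule$min_count %||% 5,
                                 pooled_label = prule$pooled_label %||% "POOLED")
      pooled <- names(pr$mapping)[pr$mapping != names(pr$mapping)]
      study$tables[[dom]] <- pr$table
      log <- log_append(log, dom, pvar, "generalise.pool", "pooled",
                        sprintf("min_count=%d; %d categor(ies) pooled",
                                prule$min_count %||% 5, length(pooled)),
                        n = length(pooled))
    }
  }
  for (arule in gcfg$anthropometry %||% list()) {
    avar <- arule$variable
    spec <- bin_spec(arule$width, anchor = arule$anchor %||% 0,
                     style = arule$style %||% "decimal")
    for (dom in names(study$tables)) {
      if (!avar %in% names(study$tables[[dom]])) next
      study$tables[[dom]][[avar]] <-
        as.character(bin_value(study$tables[[dom]][[avar]], spec))
      study$kinds[[dom]][[avar]] <- "text"
      log <- log_append(log, dom, avar, "generalise.bin", "transformed",
                        sprintf("binned, width %s", arule$width),
                        n = sum(!is.na(study$tables[[dom]][[avar]])))
    }
  }
  if (!is.null(gcfg$zip)) {
    zvar <- gcfg$zip$variable %||% "ZIP"
    for (dom in names(study$tables)) {
      if (!zvar %in% names(study$tables[[dom]])) next
      z <- truncate_zip(study$tables[[dom]][[zvar]],
                        retention_permitted =
                          isTRUE(gcfg$zip$retention_permitted))
      study$tables[[dom]][[zvar]] <- as.character(z)
      log <- log_append(log, dom, zvar, "generalise.zip", "transformed",
                        if (isTRUE(gcfg$zip$retention_permitted))
                          "truncated to three leading digits"
                        else "removed (retention not permitted)",
                        n = sum(!is.na(study$tables[[dom]][[zvar]])))
    }
  }

  # 6. free-text scrub -------------------------------------------------------
  scrub_targets <- config$scrub$targets %||% list()
  if (length(scrub_targets)) {
    for (dom in names(study$tables)) {
      present <- intersect(names(scrub_targets), names(study$tables[[dom]]))
      if (!length(present)) next
      sv <- scrub_verbatim(study$tables[[dom]], scrub_targets[present])
      study$tables[[dom]] <- sv$table
      study$kinds[[dom]] <-
        study$kinds[[dom]][names(study$kinds[[dom]]) %in%
                             names(sv$table)]
      sl <- sv$log; if (nrow(sl)) sl$table <- dom
      log <- rbind(log, sl)
      if (nrow(sv$review))
        review <- c(review, sprintf("%s.%s row %d: %s finding retained for review",
                                    dom, sv$review$variable, sv$review$record,
                                    sv$review$family))
    }
  }

  # 7. subset selection ------------------------------------------------------
  subset_note <- NULL
  if (!identical(config$subset, "all")) {
    keep <- config$subset$tables %||% names(study$tables)
    if (!study$subject_level_table %in% keep)
      stop("subset must retain the subject-level table '",
           study$subject_level_table, "'", call. = FALSE)
    for (dom in setdiff(names(study$tables), keep))
      log <- log_append(log, dom, "(all)", "subset.table", "removed",
                        "table not part of the shared subset",
                        n = nrow(study$tables[[dom]]))
    study$tables <- study$tables[keep]
    study$kinds <- study$kinds[keep]
    for (dom in names(config$subset$variables %||% list())) {
      if (!dom %in% names(study$tables)) next
      keepv <- union(config$subset$variables[[dom]],
                     c(study$subject_key, study$site_key))
      for (v in setdiff(names(study$tables[[dom]]), keepv)) {
        study$tables[[dom]][[v]] <- NULL
        study$kinds[[dom]] <-
          study$kinds[[dom]][names(study$kinds[[dom]]) != v]
        log <- log_append(log, dom, v, "subset.variable", "removed",
                          "variable not part of the shared subset", n = NA)
      }
    }
    subset_note <- paste0(
      "Only a subset of the study is shared: tables ",
      paste(names(study$tables), collapse = ", "),
      ". The full study was de-identified; unselected material is withheld, ",
      "not transformed differently.")
  } else {
    subset_note <- paste0(
      "All domain tables are shared. Providing the full set of data can ",
      "increase re-identification risk relative to a research-proposal ",
      "subset; this was an explicit configuration choice.")
  }

  # 8. residual risk ---------------------------------------------------------
  rcfg <- config$risk %||% list()
  risk <- NULL
  if (!is.null(rcfg$qi))
    risk <- assess_risk(study, rcfg$qi,
                        event_vars = rcfg$events %||% character(),
                        denom_threshold = rcfg$denom_threshold %||% 100,
                        numer_threshold = rcfg$numer_threshold %||% 3)

  # 9. key disposition, report, QC ------------------------------------------
  if (config$keys$disposition == "store" && !is.null(config$keys$out_dir)) {
    dir.create(config$keys$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (scope in intersect(names(keys), c("subject", "site")))
      write_code_key(keys[[scope]],
                     file.path(config$keys$out_dir,
                               paste0("code_key_", scope, ".json")))
  }
  if (config$keys$disposition == "destroy")
    for (scope in intersect(names(keys), c("subject", "site")))
      keys[[scope]] <- destroy_key(keys[[scope]])

  log <- stamp_log(log, timestamp)
  report <- build_report(log, risk = risk, subset_note = subset_note,
                         seed_fingerprints = fingerprints,
                         timestamp = timestamp)
  if (length(needs_review))
    report$warnings <- c(report$warnings,
                         paste0("undeclared variable(s) need manual review: ",
                                paste(needs_review, collapse = ", ")))
  if (length(review))
    report$warnings <- c(report$warnings, review)
  qc <- qc_verify(original, study, classification, log)

  list(study = study, log = log, risk = risk, keys = keys, qc = qc,
       report = report, review = review, classification = classification)
}

#' Default pipeline configuration for generator-shaped studies
#'
#' A complete configuration matching the column layout of
#' [generate_study()]: direct-identifier columns removed, subject and site
#' codes re-coded, study-day dates with month-midpoint partial handling,
#' age derivation with over-89 top-coding, race mapping, ethnicity removal,
#' small-site pooling, weight binning, ZIP removal, verbatim adverse-event
#' text dropped in favour of the coded term, all tables shared, and risk
#' assessed over sex/race/country with the coded AE term as event variable.
#' Intended as a worked starting point to adapt per study.
#'
#' @param seed Integer seed used for all randomised rules.
#' @param date_method `"study_day"` (default) or `"offset"`.
#' @param key_disposition `"store"` or `"destroy"`; deliberately has no
#'   default in [run_deidentify()], but this helper picks `"destroy"`.
#' @return A configuration list for [run_deidentify()].
#' @export
default_pipeline_config <- function(seed, date_method = "study_day",
                                    key_disposition = "destroy") {
  list(
    classification = list(
      SUBJID = "subject-identifier",
      SITEID = "site-identifier",
      NAME  = list(role = "other", hipaa_class = "direct",
                   registry_code = "A", retain_policy = "remove"),
      EMAIL = list(role = "other", hipaa_class = "direct",
                   registry_code = "F", retain_policy = "remove"),
      PHONE = list(role = "other", hipaa_class = "direct",
                   registry_code = "D", retain_policy = "remove"),
      SSN   = list(role = "other", hipaa_class = "direct",
                   registry_code = "G", retain_policy = "remove"),
      ZIP   = list(role = "quasi-identifier", retain_policy = "generalise"),
      BRTHDTC = "date-of-birth",
      RFSTDTC = "calendar-date", AESTDTC = "calendar-date",
      AEENDTC = "calendar-date", VSDTC = "calendar-date",
      LBDTC = "calendar-date", DSSTDTC = "calendar-date",
      AETERM = "verbatim-text", AEDECOD = "coded-term",
      COUNTRY = "quasi-identifier", RACE = "quasi-identifier",
      ETHNIC = "quasi-identifier", SEX = "quasi-identifier",
      HEIGHT = "measurement", WEIGHT = "measurement",
      ARM = "other", VISITNUM = "other", VSTESTCD = "other",
      VSORRES = "measurement", LBTESTCD = "other", LBORRES = "measurement",
      DSDECOD = "coded-term"),
    keys = list(seed = seed, disposition = key_disposition,
                subject_template = "S#####", site_template = "T###"),
    dates = list(method = date_method,
                 reference = list(mode = "per-subject", table = "DM",
                                  variable = "RFSTDTC", fallback = "error"),
                 partial_policy = "month-midpoint",
                 offset = list(lo = -30, hi = 30, exclude_zero = TRUE,
                               constrain_to_trial_range = TRUE)),
    generalise = list(
      age = list(variable = "AGE", cap = 89, label = ">89", bin_width = 5),
      race = list(variable = "RACE"),
      ethnicity = list(variable = "ETHNIC", remove = TRUE),
      pooling = list(list(variable = "SITEID", min_count = 5,
                          pooled_label = "POOLED")),
      anthropometry = list(list(variable = "WEIGHT", width = 10,
                                style = "decimal")),
      zip = list(variable = "ZIP", retention_permitted = FALSE)),
    scrub = list(targets = list(
      AETERM = list(mode = "drop-variable", coded_counterpart = "AEDECOD"))),
    subset = "all",
    risk = list(qi = c("SEX", "RACE", "COUNTRY"), events = c("AE.AEDECOD"),
                denom_threshold = 100, numer_threshold = 3),
    report = list(timestamp = "1970-01-01T00:00:00Z"))
}
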