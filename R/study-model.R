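# Core data model: a study is a named collection of domain tables (DM, AE, ...)
# sharing a subject key. All cell values are held as character strings; declared
# value kinds (text / integer / decimal / calendar-date / partial-date) drive
# validation and the transforms, never silent coercion.

VALUE_KINDS <- c("text", "integer", "decimal", "calendar-date", "partial-date")

#' Construct a study object
#'
#' A study bundles one or more domain tables (in the style of CDISC SDTM
#' domains such as DM, AE, VS, LB) that share a subject key, together with
#' per-variable value kinds, an optional site key, a per-subject or
#' trial-level reference-date designation and free-form provenance metadata.
#'
#' All table columns are stored as character vectors with `NA` for missing;
#' declared kinds describe how values are to be interpreted, and values that
#' do not conform to their kind are kept verbatim rather than coerced.
#'
#' @param tables Named list of data frames, one per domain. Names must be
#'   unique. All columns are converted to character.
#' @param subject_key Name of the subject identifier variable; must be present
#'   in every table.
#' @param site_key Optional name of the site identifier variable.
#' @param kinds Named list (by domain) of named character vectors mapping
#'   variable names to value kinds. Undeclared variables default to `"text"`.
#' @param subject_level_table Domain holding one row per subject (defaults to
#'   `"DM"` when present, else the first table). Referential integrity is
#'   checked against it.
#' @param reference_date Either `list(mode = "per-subject", table =, variable =)`
#'   or `list(mode = "trial-level", date = "YYYY-MM-DD")`, or `NULL`.
#' @param provenance Free-form list (source paths, load timestamp, config
#'   fingerprint).
#' @param validate Check study invariants (default `TRUE`).
#' @return An object of class `trial_study`.
#' @export
new_study <- function(tables, subject_key, site_key = NULL, kinds = list(),
                      subject_level_table = NULL, reference_date = NULL,
                      provenance = list(), validate = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("every table must be named by its domain", call. = FALSE)
  if (anyDuplicated(names(tables)))
    stop("duplicate domain name: ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "),
         call. = FALSE)
  tables <- lapply(tables, as_character_table)
  if (is.null(subject_level_table))
    subject_level_table <- if ("DM" %in% names(tables)) "DM" else names(tables)[1]
  kinds <- complete_kinds(tables, kinds)
  study <- structure(
    list(tables = tables,
         kinds = kinds,
         subject_key = subject_key,
         site_key = site_key,
         subject_level_table = subject_level_table,
         reference_date = reference_date,
         provenance = provenance),
    class = "trial_study")
  if (validate) validate_study(study)
  study
}

as_character_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate variable name within a table", call. = FALSE)
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  })
  rownames(df) <- NULL
  df
}

complete_kinds <- function(tables, kinds) {
  out <- list()
  for (dom in names(tables)) {
    k <- kinds[[dom]]
    full <- stats::setNames(rep("text", ncol(tables[[dom]])), names(tables[[dom]]))
    if (!is.null(k)) {
      bad <- setdiff(k, VALUE_KINDS)
      if (length(bad)) stop("unknown value kind: ", paste(bad, collapse = ", "),
                            call. = FALSE)
      known <- intersect(names(k), names(full))
      full[known] <- k[known]
    }
    out[[dom]] <- full
  }
  out
}

#' Validate study invariants
#'
#' Checks that the subject key exists in every table, that calendar-date
#' declared values are valid ISO 8601 dates or missing (violations are
#' reported as warnings, values stay verbatim), and that every subject seen
#' in an event-level table also appears in the subject-level table.
#'
#' @param study A `trial_study`.
#' @return The study, invisibly. Hard errors on structural violations;
#'   warnings for non-conforming cell values.
#' @export
validate_study <- function(study) {
  for (dom in names(study$tables)) {
    tab <- study$tables[[dom]]
    if (!study$subject_key %in% names(tab))
      stop("table '", dom, "' is missing the subject-key column '",
           study$subject_key, "'", call. = FALSE)
  }
  slt <- study$subject_level_table
  if (!slt %in% names(study$tables))
    stop("subject-level table '", slt, "' not found", call. = FALSE)
  subjects <- study$tables[[slt]][[study$subject_key]]
  for (dom in setdiff(names(study$tables), slt)) {
    seen <- unique(stats::na.omit(study$tables[[dom]][[study$subject_key]]))
    orphan <- setdiff(seen, subjects)
    if (length(orphan))
      stop("table '", dom, "' contains subjects absent from '", slt, "': ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  for (dom in names(study$tables)) {
    k <- study$kinds[[dom]]
    for (v in names(k)[k == "calendar-date"]) {
      x <- study$tables[[dom]][[v]]
      bad <- !is.na(x) & is.na(parse_iso_date(x))
      if (any(bad))
        warning(sum(bad), " value(s) in ", dom, ".", v,
                " declared calendar-date do not parse as ISO dates; kept as text",
                call. = FALSE)
    }
  }
  invisible(study)
}

#' Parse ISO 8601 calendar dates strictly
#'
#' Accepts only complete `YYYY-MM-DD` strings that denote real calendar days;
#' anything else (including partial dates) becomes `NA`.
#'
#' @param x Character vector.
#' @return A `Date` vector with `NA` for non-conforming values.
#' @export
parse_iso_date <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Is a value a partial (year or year-month) date?
#'
#' @param x Character vector.
#' @return Logical vector; `TRUE` for `YYYY` or `YYYY-MM` shaped values.
#' @export
is_partial_date <- function(x) {
  !is.na(x) & grepl("^\\d{4}(-\\d{2})?$", as.character(x)) &
    !grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x))
}

#' Read a multi-domain study from CSV files
#'
#' Reads one RFC 4180 CSV per domain (UTF-8, header row mandatory, empty
#' string = missing) and assembles a validated study. Values declared
#' `calendar-date` that do not parse as real ISO dates are kept verbatim and
#' reported as warnings, never coerced.
#'
#' @param paths Character vector of CSV paths. Domain names are taken from
#'   `names(paths)` when present, else from the upper-cased file basename.
#' @param config Study-layout declaration: a list (or path to a YAML/JSON
#'   file) with `subject_key`, optional `site_key`, optional
#'   `subject_level_table`, optional `reference_date`, and optional `kinds`
#'   (per-domain named vectors of value kinds).
#' @return A `trial_study`.
#' @export
read_study <- function(paths, config) {
  config <- load_config(config)
  if (is.null(config$subject_key))
    stop("config must declare 'subject_key'", call. = FALSE)
  doms <- names(paths)
  if (is.null(doms) || any(!nzchar(doms)))
    doms <- toupper(sub("\\.[Cc][Ss][Vv]$", "", basename(paths)))
  if (anyDuplicated(doms))
    stop("duplicate domain name among inputs: ",
         paste(unique(doms[duplicated(doms)]), collapse = ", "), call. = FALSE)
  tables <- list()
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i]))
      stop("file not found: ", paths[i], call. = FALSE)
    tables[[doms[i]]] <- utils::read.csv(
      paths[i], colClasses = "character", check.names = FALSE,
      na.strings = "", fileEncoding = "UTF-8")
  }
  new_study(tables,
            subject_key = config$subject_key,
            site_key = config$site_key,
            kinds = config$kinds %||% list(),
            subject_level_table = config$subject_level_table,
            reference_date = config$reference_date,
            provenance = list(source = unname(paths),
                              loaded = format(Sys.time(), tz = "UTC")))
}

#' Write a study to one CSV per domain
#'
#' Emits RFC 4180 CSVs (UTF-8, header row, missing values as empty strings)
#' such that `read_study()` on the written files reproduces the study
#' table-for-table, value-for-value.
#'
#' @param study A `trial_study`.
#' @param out_dir Output directory, created if needed.
#' @param overwrite Allow replacing existing files (default `FALSE`; a
#'   collision is a hard error otherwise).
#' @return Invisibly, the written file paths (named by domain).
#' @export
write_study <- function(study, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(study$tables), ".csv"))
  names(paths) <- names(study$tables)
  if (!overwrite) {
    clash <- paths[file.exists(paths)]
    if (length(clash))
      stop("refusing to overwrite existing file(s): ",
           paste(clash, collapse = ", "), " (set overwrite = TRUE)",
           call. = FALSE)
  }
  for (dom in names(study$tables))
    utils::write.csv(study$tables[[dom]], paths[[dom]], row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", quote = TRUE)
  invisible(paths)
}

#' Structural diff between two studies
#'
#' Compares two studies domain by domain and reports one change record per
#' (table, variable) whose content differs: variables removed or added, and
#' variables whose values changed. Value changes are classified as
#' `"recoded"` for the subject/site key, `"blanked"` when every previously
#' observed value became missing, and `"unchanged-values-differ"` otherwise.
#' Identical variables are absent from the result. This is the raw evidence
#' the quality-control step checks against the transformation log.
#'
#' @param before,after `trial_study` objects over the same domain names.
#' @return A data frame with columns `table`, `variable`, `kind`.
#' @export
diff_studies <- function(before, after) {
  b <- names(before$tables); a <- names(after$tables)
  if (!setequal(b, a)) {
    stop("domain sets differ; only in before: {",
         paste(setdiff(b, a), collapse = ", "), "}; only in after: {",
         paste(setdiff(a, b), collapse = ", "), "}", call. = FALSE)
  }
  recs <- list()
  add <- function(tab, var, kind)
    recs[[length(recs) + 1L]] <<- data.frame(table = tab, variable = var,
                                             kind = kind)
  for (dom in b) {
    tb <- before$tables[[dom]]; ta <- after$tables[[dom]]
    for (v in setdiff(names(tb), names(ta))) add(dom, v, "removed")
    for (v in setdiff(names(ta), names(tb))) add(dom, v, "added")
    for (v in intersect(names(tb), names(ta))) {
      x <- tb[[v]]; y <- ta[[v]]
      same <- length(x) == length(y) &&
        all((is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y))
      if (same) next
      kind <- if (v %in% c(before$subject_key, before$site_key)) "recoded"
      else if (length(y) == 0L || all(is.na(y))) "blanked"
      else "unchanged-values-differ"
      add(dom, v, kind)
    }
  }
  if (!length(recs))
    return(data.frame(table = character(), variable = character(),
                      kind = character()))
  do.call(rbind, recs)
}

#' Test two studies for table-by-table value equality
#'
#' @param a,b `trial_study` objects.
#' @return `TRUE` when both have the same domains, variables and cell values.
#' @export
studies_equal <- function(a, b) {
  if (!setequal(names(a$tables), names(b$tables))) return(FALSE)
  for (dom in names(a$tables)) {
    ta <- a$tables[[dom]]; tb <- b$tables[[dom]]
    if (!identical(names(ta), names(tb)) || nrow(ta) != nrow(tb)) return(FALSE)
    for (v in names(ta)) {
      x <- ta[[v]]; y <- tb[[v]]
      if (!all((is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)))
        return(FALSE)
    }
  }
  TRUE
}

#' @export
print.trial_study <- function(x, ...) {
  cat("<trial_study> ", length(x$tables), " domain(s), subject key '",
      x$subject_key, "'\n", sep = "")
  for (dom in names(x$tables))
    cat(sprintf("  %-4s %5d records x %d variables\n", dom,
                nrow(x$tables[[dom]]), ncol(x$tables[[dom]])))
  invisible(x)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
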