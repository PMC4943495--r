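# Transformation log, researcher-facing report, and the adversarial quality
# control step. QC compares input to output directly rather than trusting
# the log: the process documents itself, and a separate check verifies it.

empty_log <- function() {
  data.frame(table = character(), variable = character(),
             rule_id = character(), action = character(),
             parameters = character(), n_affected = integer(),
             timestamp = character())
}

log_append <- function(log, table, variable, rule_id, action, parameters,
                       n = NA_integer_, timestamp = "") {
  rbind(log, data.frame(table = table, variable = variable,
                        rule_id = rule_id, action = action,
                        parameters = parameters,
                        n_affected = as.integer(n),
                        timestamp = timestamp))
}

stamp_log <- function(log, timestamp) {
  if (nrow(log)) log$timestamp <- timestamp
  log
}

#' Build the de-identification report
#'
#' Renders the transformation log and risk assessment into the
#' documentation that accompanies shared data: per table, the variables
#' removed, altered (and how), pooled labels, the date method, the risk
#' summary with its thresholds, seed fingerprints, the Safe Harbor
#' attestation line, and — when only a subset of the study is shared — the
#' subset note. An empty run is reported as such, flagged as a warning.
#'
#' @param log Transformation log data frame.
#' @param risk Optional `risk_report`.
#' @param subset_note Optional text describing which tables/variables were
#'   shared and why.
#' @param seed_fingerprints Optional named character vector of seed
#'   fingerprints (subject key, site key, offsets, ...).
#' @param timestamp Pinned report timestamp (character). Using a fixed
#'   value makes report generation byte-reproducible.
#' @return A `deid_report`: list with `generated`, `entries`, `risk`,
#'   `subset_note`, `seed_fingerprints`, `attestation`, `warnings`.
#' @export
build_report <- function(log, risk = NULL, subset_note = NULL,
                         seed_fingerprints = NULL, timestamp = "") {
  warnings <- character(0)
  if (nrow(log) == 0L)
    warnings <- c(warnings, "empty run: no transformations were applied")
  structure(
    list(generated = timestamp,
         entries = log,
         risk = risk,
         subset_note = subset_note,
         seed_fingerprints = as.list(seed_fingerprints),
         attestation = attr(builtin_registry(), "attestation"),
         warnings = warnings),
    class = "deid_report")
}

#' Render a report as Markdown
#'
#' @param report A `deid_report`.
#' @return A single character string of Markdown.
#' @export
format_report_md <- function(report) {
  out <- c("# De-identification report", "",
           paste0("Generated: ", if (nzchar(report$generated))
             report$generated else "(unpinned)"), "")
  for (w in report$warnings) out <- c(out, paste0("**Warning:** ", w), "")
  log <- report$entries
  for (dom in unique(log$table)) {
    sub <- log[which(log$table == dom | (is.na(log$table) & is.na(dom))), ,
               drop = FALSE]
    out <- c(out, paste0("## Table ", if (is.na(dom)) "(unscoped)" else dom), "")
    for (i in seq_len(nrow(sub)))
      out <- c(out, sprintf("- `%s` [%s] %s: %s (n=%s)",
                            sub$variable[i], sub$rule_id[i], sub$action[i],
                            sub$parameters[i], sub$n_affected[i]))
    out <- c(out, "")
  }
  if (!is.null(report$risk)) {
    r <- report$risk
    out <- c(out, "## Residual risk", "",
             sprintf("- Quasi-identifiers: %s", paste(r$qi, collapse = ", ")),
             sprintf("- Subjects: %d; equivalence classes: %d; k = %d; unique subjects: %d",
                     r$n_subjects, length(r$class_sizes), r$k, r$uniques),
             sprintf("- Small-cell thresholds: denominator < %d, numerator < %d; flags raised: %d",
                     r$thresholds$denominator, r$thresholds$numerator,
                     nrow(r$flags)),
             "")
  }
  if (length(report$seed_fingerprints))
    out <- c(out, "## Seed fingerprints", "",
             sprintf("- %s: `%s`", names(report$seed_fingerprints),
                     unlist(report$seed_fingerprints)), "")
  if (!is.null(report$subset_note))
    out <- c(out, "## Data subset", "", report$subset_note, "")
  out <- c(out, "## Attestation", "", report$attestation, "")
  paste(out, collapse = "\n")
}

#' Write a report to disk
#'
#' Emits the same report in machine-readable (`report.json`) and
#' human-readable (`report.md`) form.
#'
#' @param report A `deid_report`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  md_path <- file.path(out_dir, "report.md")
  obj <- unclass(report)
  if (!is.null(obj$risk)) {
    obj$risk <- unclass(obj$risk)
    obj$risk$class_sizes <- as.integer(obj$risk$class_sizes)
  }
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  writeLines(format_report_md(report), md_path)
  invisible(c(json = json_path, md = md_path))
}

qc_finding <- function(check_id, severity, message, location = "") {
  data.frame(check_id = check_id, severity = severity, message = message,
             location = location)
}

#' Quality-control verification of a de-identification run
#'
#' Adversarial check of the de-identified study against the original,
#' independent of the transformation process itself. Verifies at minimum:
#' (a) no variable classified as a direct identifier survives
#' unremoved/unrecoded/untransformed; (b) no raw calendar dates remain in
#' date-rule variables (values equal to an original date are failures;
#' offset-method variables must differ cell-by-cell); (c) subject codes are
#' fully re-coded with zero overlap with the original codes; (d) verbatim
#' scrub targets are absent or blank; (e) every observed difference between
#' input and output is covered by a log entry — no silent changes. Each
#' check yields a finding (`fail`, `warn` or `info`).
#'
#' @param original,deidentified `trial_study` objects (the de-identified
#'   study may lack tables dropped by subsetting, provided the log records
#'   them).
#' @param classification Output of [classify_variables()] on the original.
#' @param log Transformation log of the run.
#' @return Data frame of findings with columns `check_id`, `severity`,
#'   `message`, `location`. Any `fail` row means the run must not ship.
#' @export
qc_verify <- function(original, deidentified, classification, log) {
  f <- list()
  push <- function(x) f[[length(f) + 1L]] <<- x
  logged_pairs <- paste(log$table, log$variable)

  # (a) direct identifiers must not survive with original values
  direct <- names(classification)[vapply(classification,
                                         function(m) m$hipaa_class == "direct",
                                         logical(1))]
  bad_a <- character(0)
  for (dom in names(deidentified$tables)) {
    ta <- deidentified$tables[[dom]]
    tb <- original$tables[[dom]]
    if (is.null(tb)) next
    for (v in intersect(direct, names(ta))) {
      if (!v %in% names(tb)) next
      x <- tb[[v]]; y <- ta[[v]]
      if (length(x) == length(y) &&
          any(!is.na(x) & !is.na(y) & x == y))
        bad_a <- c(bad_a, paste0(dom, ".", v))
    }
  }
  push(if (length(bad_a))
    qc_finding("direct-identifiers-removed", "fail",
               "direct identifier(s) survive with original values",
               paste(bad_a, collapse = ", "))
    else qc_finding("direct-identifiers-removed", "info",
                    "no direct identifier survives with original values"))

  # (b) no raw calendar dates in date-rule variables
  bad_b <- character(0)
  for (dom in names(deidentified$tables)) {
    tb <- original$tables[[dom]]
    if (is.null(tb)) next
    k <- original$kinds[[dom]]
    for (v in names(k)[k == "calendar-date"]) {
      meta <- classification[[v]]
      if (!is.null(meta) && meta$retain_policy == "keep") next
      ta <- deidentified$tables[[dom]]
      if (!v %in% names(ta)) next  # removed or renamed to a study-day var
      x <- tb[[v]]; y <- ta[[v]]
      same <- length(x) == length(y) & any(!is.na(x) & !is.na(y) & x == y)
      if (isTRUE(same)) bad_b <- c(bad_b, paste0(dom, ".", v))
    }
  }
  push(if (length(bad_b))
    qc_finding("no-raw-dates", "fail",
               "original calendar date value(s) remain",
               paste(bad_b, collapse = ", "))
    else qc_finding("no-raw-dates", "info",
                    "no original calendar date values remain in date-rule variables"))

  # (c) subject codes fully re-coded, zero overlap with originals
  old_codes <- unique(stats::na.omit(unlist(
    lapply(original$tables, function(t) t[[original$subject_key]]),
    use.names = FALSE)))
  overlap <- character(0)
  for (dom in names(deidentified$tables)) {
    cur <- deidentified$tables[[dom]][[deidentified$subject_key]]
    hit <- intersect(unique(stats::na.omit(cur)), old_codes)
    if (length(hit))
      overlap <- c(overlap, paste0(dom, ": ",
                                   paste(utils::head(hit, 5), collapse = ", ")))
  }
  push(if (length(overlap))
    qc_finding("subjects-recoded", "fail",
               "original subject code(s) still present",
               paste(overlap, collapse = "; "))
    else qc_finding("subjects-recoded", "info",
                    "subject codes fully re-coded; no overlap with originals"))

  # (d) verbatim targets absent or blank
  verbatim <- names(classification)[vapply(classification,
                                           function(m) m$role == "verbatim-text",
                                           logical(1))]
  bad_d <- character(0)
  for (dom in names(deidentified$tables)) {
    ta <- deidentified$tables[[dom]]
    for (v in intersect(verbatim, names(ta)))
      if (any(!is.na(ta[[v]]))) {
        # review mode may retain text; it must then carry no scanner findings
        if (nrow(scan_free_values(ta, variables = v)))
          bad_d <- c(bad_d, paste0(dom, ".", v))
      }
  }
  push(if (length(bad_d))
    qc_finding("verbatim-scrubbed", "fail",
               "verbatim text with identifier-like content remains",
               paste(bad_d, collapse = ", "))
    else qc_finding("verbatim-scrubbed", "info",
                    "verbatim targets absent, blank, or free of findings"))

  # (e) every observed change is covered by the log
  shared <- intersect(names(original$tables), names(deidentified$tables))
  dropped <- setdiff(names(original$tables), shared)
  uncovered <- character(0)
  for (dom in dropped) {
    if (!any(log$table == dom & log$rule_id %in%
             c("subset.table", "pipeline.subset"), na.rm = TRUE))
      uncovered <- c(uncovered, paste0(dom, " (table dropped)"))
  }
  if (length(shared)) {
    bsub <- original; bsub$tables <- original$tables[shared]
    bsub$kinds <- original$kinds[shared]
    asub <- deidentified; asub$tables <- deidentified$tables[shared]
    asub$kinds <- deidentified$kinds[shared]
    d <- diff_studies(bsub, asub)
    for (i in seq_len(nrow(d))) {
      pair_scoped <- paste(d$table[i], d$variable[i])
      pair_unscoped <- paste(NA, d$variable[i])
      if (!pair_scoped %in% logged_pairs && !pair_unscoped %in% logged_pairs &&
          !paste("(all)", d$variable[i]) %in% logged_pairs)
        uncovered <- c(uncovered, paste0(d$table[i], ".", d$variable[i]))
    }
  }
  push(if (length(uncovered))
    qc_finding("log-covers-diff", "fail",
               "change(s) not covered by the transformation log",
               paste(unique(uncovered), collapse = ", "))
    else qc_finding("log-covers-diff", "info",
                    "every observed change is covered by the log"))

  do.call(rbind, f)
}

#' Did a QC run pass?
#'
#' @param findings Output of [qc_verify()].
#' @return `TRUE` when no finding has severity `fail`.
#' @export
qc_passed <- function(findings) !any(findings$severity == "fail")
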