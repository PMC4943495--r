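# Residual re-identification risk of a (de-identified) study: equivalence
# classes over declared quasi-identifiers, k-anonymity, uniqueness, and the
# small-denominator / small-numerator screens. Risk is reported, never
# auto-remediated: blanket deletion of rare events would destroy exactly
# the safety information researchers need.

# Resolve a quasi-identifier declaration to a one-row-per-subject frame.
# qi: character vector of "TABLE.VAR" or bare variable names (looked up in
# the subject-level table first, then uniquely across tables).
qi_frame <- function(study, qi) {
  slt <- study$subject_level_table
  subjects <- study$tables[[slt]][[study$subject_key]]
  out <- data.frame(.subject = subjects)
  for (q in qi) {
    if (grepl(".", q, fixed = TRUE)) {
      parts <- strsplit(q, ".", fixed = TRUE)[[1]]
      dom <- parts[1]; v <- paste(parts[-1], collapse = ".")
    } else {
      v <- q
      dom <- NULL
      for (d in c(slt, setdiff(names(study$tables), slt)))
        if (v %in% names(study$tables[[d]])) { dom <- d; break }
      if (is.null(dom))
        stop("quasi-identifier '", q, "' not found in any table", call. = FALSE)
    }
    tab <- study$tables[[dom]]
    if (is.null(tab) || !v %in% names(tab))
      stop("quasi-identifier '", q, "' not found", call. = FALSE)
    per_subj <- tapply(tab[[v]], tab[[study$subject_key]],
                       function(x) length(unique(x)))
    if (any(per_subj > 1L, na.rm = TRUE))
      stop("quasi-identifier '", q, "' is event-level (multiple values per ",
           "subject) and no reduction rule applies; reduce it to subject ",
           "level first", call. = FALSE)
    idx <- match(subjects, tab[[study$subject_key]])
    out[[q]] <- tab[[v]][idx]
  }
  out
}

#' Equivalence-class sizes over a quasi-identifier set
#'
#' Partitions subjects by exact equality on the declared quasi-identifier
#' tuple. Missing is a category of its own: missingness patterns can
#' themselves identify, so they are counted deterministically rather than
#' merged or dropped.
#'
#' @param study A `trial_study`.
#' @param qi Character vector of quasi-identifier variables (bare names or
#'   `"TABLE.VAR"`); must be subject-level. An empty set yields one class
#'   holding every subject.
#' @return Sorted integer vector of class sizes (a multiset; sums to the
#'   number of subjects).
#' @export
equivalence_classes <- function(study, qi) {
  f <- qi_frame(study, qi)
  if (length(qi) == 0L) return(nrow(f))
  key <- do.call(paste, c(lapply(f[qi], function(x)
    ifelse(is.na(x), "\x01<NA>", x)), sep = "\x1f"))
  sort(as.integer(table(key)))
}

#' k-anonymity of a study under a quasi-identifier set
#'
#' The minimum equivalence-class size: `k = 1` means at least one subject
#' is unique on the declared attributes. Adding a variable to the set can
#' only split classes, so k is monotone non-increasing under refinement.
#'
#' @inheritParams equivalence_classes
#' @return A positive integer.
#' @export
k_anonymity <- function(study, qi) {
  n <- nrow(study$tables[[study$subject_level_table]])
  if (n == 0L) stop("study has no subjects", call. = FALSE)
  min(equivalence_classes(study, qi))
}

#' Flag small denominators and small numerators
#'
#' Screens for the two small-cell risks: quasi-identifier category
#' combinations with fewer than `denom_threshold` subjects (small
#' denominators, default < 100), and event terms carried by fewer than
#' `numer_threshold` distinct subjects (small numerators, default < 3,
#' e.g. rare coded adverse events). Both comparisons are strict. Flags are
#' advisory and carry the observed counts and thresholds; nothing is
#' deleted.
#'
#' @inheritParams equivalence_classes
#' @param event_vars Character vector of event-term variables
#'   (`"TABLE.VAR"` or bare names, e.g. `"AE.AEDECOD"`); distinct subjects
#'   are counted per term.
#' @param denom_threshold Population-size threshold (default 100).
#' @param numer_threshold Event-count threshold (default 3).
#' @return Data frame with columns `kind` (`"denominator"`/`"numerator"`),
#'   `cell`, `count`, `threshold`; zero rows when nothing is flagged.
#' @export
flag_small_cells <- function(study, qi, event_vars = character(),
                             denom_threshold = 100, numer_threshold = 3) {
  stopifnot(denom_threshold >= 1, numer_threshold >= 1)
  flags <- list()
  if (length(qi)) {
    f <- qi_frame(study, qi)
    key <- do.call(paste, c(lapply(f[qi], function(x)
      ifelse(is.na(x), "<NA>", x)), sep = "/"))
    tab <- table(key)
    for (cell in names(tab)[tab < denom_threshold])
      flags[[length(flags) + 1L]] <- data.frame(
        kind = "denominator",
        cell = paste0(paste(qi, collapse = "/"), " = ", cell),
        count = as.integer(tab[[cell]]), threshold = denom_threshold)
  }
  for (ev in event_vars) {
    if (grepl(".", ev, fixed = TRUE)) {
      parts <- strsplit(ev, ".", fixed = TRUE)[[1]]
      dom <- parts[1]; v <- paste(parts[-1], collapse = ".")
    } else {
      v <- ev; dom <- NULL
      for (d in names(study$tables))
        if (v %in% names(study$tables[[d]])) { dom <- d; break }
      if (is.null(dom))
        stop("event variable '", ev, "' not found", call. = FALSE)
    }
    tab <- study$tables[[dom]]
    if (is.null(tab) || !v %in% names(tab))
      stop("event variable '", ev, "' not found", call. = FALSE)
    obs <- !is.na(tab[[v]])
    counts <- tapply(tab[[study$subject_key]][obs], tab[[v]][obs],
                     function(s) length(unique(s)))
    small <- counts[counts > 0 & counts < numer_threshold]
    for (term in names(small))
      flags[[length(flags) + 1L]] <- data.frame(
        kind = "numerator",
        cell = paste0(ev, " = ", term),
        count = as.integer(small[[term]]), threshold = numer_threshold)
  }
  if (!length(flags))
    return(data.frame(kind = character(), cell = character(),
                      count = integer(), threshold = integer()))
  do.call(rbind, flags)
}

#' Assemble a risk report
#'
#' Runs [equivalence_classes()], [k_anonymity()] and [flag_small_cells()]
#' and bundles the results. The acceptable-risk threshold is the data
#' holder's responsibility; this report surfaces the quantities on which
#' that judgement rests.
#'
#' @inheritParams flag_small_cells
#' @return A `risk_report`: list with `qi`, `class_sizes`, `k`, `uniques`,
#'   `n_subjects`, `flags`, `thresholds`.
#' @export
assess_risk <- function(study, qi, event_vars = character(),
                        denom_threshold = 100, numer_threshold = 3) {
  sizes <- equivalence_classes(study, qi)
  structure(
    list(qi = qi,
         class_sizes = sizes,
         k = min(sizes),
         uniques = sum(sizes == 1L),
         n_subjects = sum(sizes),
         flags = flag_small_cells(study, qi, event_vars,
                                  denom_threshold, numer_threshold),
         thresholds = list(denominator = denom_threshold,
                           numerator = numer_threshold)),
    class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> n=", x$n_subjects, " classes=", length(x$class_sizes),
      " k=", x$k, " uniques=", x$uniques, " flags=", nrow(x$flags), "\n",
      sep = "")
  invisible(x)
}
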