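# HIPAA Safe Harbor direct-identifier registry, declaration-driven variable
# classification, and a regex scanner for identifier-like values in cells.
# The scanner flags; it never deletes or reclassifies — classification is
# declaration-first and findings feed a human-reviewable report.

REGISTRY <- data.frame(
  code = LETTERS[1:18],
  label = c(
    "Name",
    "Geographic subdivisions smaller than a state",
    "All elements of dates (except year) directly related to an individual; ages over 89",
    "Telephone numbers",
    "Fax numbers",
    "Email addresses",
    "Social security numbers",
    "Medical record numbers",
    "Health plan beneficiary numbers",
    "Account numbers",
    "Certificate/licence numbers",
    "Vehicle identifiers and serial numbers, including license plate numbers",
    "Device identifiers and serial numbers",
    "Web Universal Resource Locators (URLs)",
    "Internet Protocol (IP) addresses",
    "Biometric identifiers, including finger and voice prints",
    "Full-face photographs and any comparable images",
    "Any other unique identifying number, characteristic, or code"),
  detection = c("name-like", "zip", "date-like", "phone", "phone", "email",
                "ssn-like", "account-like", "account-like", "account-like",
                "none", "none", "none", "url", "ip", "none", "none", "none"),
  stringsAsFactors = FALSE
)
# Safe Harbor's final item ("S" in some renderings) is not an identifier but
# the covered entity's "no actual knowledge" condition — a governance
# attestation carried into reports, never computed on data.
ATTESTATION_CONDITION <- paste(
  "The covered entity does not have actual knowledge that the remaining",
  "information could be used alone or in combination with other information",
  "to identify an individual who is a subject of the information.")
attr(REGISTRY, "attestation") <- ATTESTATION_CONDITION

# Pattern families used by the cell scanner. Conservative bias: prefer a
# false positive in the review list over a missed identifier.
SCAN_PATTERNS <- c(
  email = "[A-Za-z0-9._%+-]+@[A-Za-z0-9-]+(\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,}",
  phone = "(\\+?[0-9]{1,2}[ .-])?(\\([0-9]{3}\\)[ .-]?|[0-9]{3}[ .-])[0-9]{3}[ .-][0-9]{4}",
  url   = "(https?://|www\\.)[A-Za-z0-9._~:/?#@!$&'*+,;=%-]+",
  ip    = "\\b([0-9]{1,3}\\.){3}[0-9]{1,3}\\b",
  `ssn-like`  = "\\b[0-9]{3}-[0-9]{2}-[0-9]{4}\\b",
  `zip-like`  = "\\b[0-9]{5}(-[0-9]{4})?\\b",
  `date-like` = "\\b[0-9]{4}-[0-9]{2}-[0-9]{2}\\b"
)

SCAN_FAMILY_CODE <- c(email = "F", phone = "D", url = "N", ip = "O",
                      `ssn-like` = "G", `zip-like` = "B", `date-like` = "C")

#' The eighteen HIPAA Safe Harbor direct identifiers
#'
#' Returns the built-in registry of the eighteen Safe Harbor identifier
#' classes, coded A through R, each with a label and the value-pattern
#' family (if any) used by [scan_free_values()] to detect instances inside
#' cell text. The registry is fixed: Safe Harbor enumerates exactly these
#' classes. The accompanying "no actual knowledge" condition is a governance
#' attestation, exposed as the `attestation` attribute and carried into
#' reports as an attestation line, never computed on data.
#'
#' @return A data frame with columns `code`, `label`, `detection`
#'   (18 rows, codes A–R) and attribute `attestation`.
#' @export
builtin_registry <- function() {
  REGISTRY
}

ROLE_DEFAULTS <- list(
  `subject-identifier` = list(hipaa_class = "direct",   registry_code = "R",
                              retain_policy = "recode"),
  `site-identifier`    = list(hipaa_class = "indirect", registry_code = NA_character_,
                              retain_policy = "recode"),
  `calendar-date`      = list(hipaa_class = "direct",   registry_code = "C",
                              retain_policy = "transform"),
  `date-of-birth`      = list(hipaa_class = "direct",   registry_code = "C",
                              retain_policy = "transform"),
  `verbatim-text`      = list(hipaa_class = "indirect", registry_code = NA_character_,
                              retain_policy = "remove"),
  `coded-term`         = list(hipaa_class = "none",     registry_code = NA_character_,
                              retain_policy = "keep"),
  `quasi-identifier`   = list(hipaa_class = "indirect", registry_code = NA_character_,
                              retain_policy = "generalise"),
  `measurement`        = list(hipaa_class = "none",     registry_code = NA_character_,
                              retain_policy = "keep"),
  other                = list(hipaa_class = "none",     registry_code = NA_character_,
                              retain_policy = "keep")
)

RETAIN_POLICIES <- c("remove", "recode", "transform", "generalise", "blank", "keep")

#' Classify every study variable by role and HIPAA class
#'
#' Applies per-variable declarations to produce a complete classification of
#' every variable in every table. A declaration is either a role string
#' (`"subject-identifier"`, `"site-identifier"`, `"calendar-date"`,
#' `"date-of-birth"`, `"verbatim-text"`, `"coded-term"`,
#' `"quasi-identifier"`, `"measurement"`, `"other"`) or a list overriding
#' any of `role`, `hipaa_class`, `registry_code`, `retain_policy` (e.g. a
#' planted name column: `list(role = "other", hipaa_class = "direct",
#' registry_code = "A", retain_policy = "remove")`).
#'
#' Undeclared variables default to role `other` / class `none` / policy
#' `keep` and are listed in the `needs_review` attribute: automated
#' classification never removes the need for some manual review of
#' unexpected identifiers.
#'
#' @param study A `trial_study`.
#' @param declarations Named list: variable name -> role string or override
#'   list. Names may be plain (`"BRTHDTC"`, applied wherever the variable
#'   occurs) or scoped (`"DM.BRTHDTC"`).
#' @return Named list of `variable_meta` records, one per distinct variable
#'   name, with attribute `needs_review` (character vector of undeclared
#'   variables).
#' @export
classify_variables <- function(study, declarations = list()) {
  all_vars <- unique(unlist(lapply(study$tables, names)))
  decl_vars <- sub("^[^.]+\\.", "", names(declarations))
  missing_vars <- setdiff(decl_vars, all_vars)
  if (length(missing_vars))
    stop("declaration names variable(s) not present in the study: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  out <- list()
  declared <- character()
  for (v in all_vars) {
    idx <- which(decl_vars == v)
    if (length(idx)) {
      declared <- c(declared, v)
      out[[v]] <- build_meta(v, declarations[[idx[1]]])
    } else {
      out[[v]] <- build_meta(v, "other")
    }
  }
  attr(out, "needs_review") <- setdiff(all_vars, declared)
  out
}

build_meta <- function(name, decl) {
  if (is.character(decl)) decl <- list(role = decl)
  role <- decl$role %||% "other"
  if (!role %in% names(ROLE_DEFAULTS))
    stop("unknown role '", role, "' for variable ", name, call. = FALSE)
  d <- ROLE_DEFAULTS[[role]]
  meta <- list(
    name = name,
    role = role,
    hipaa_class = decl$hipaa_class %||% d$hipaa_class,
    registry_code = decl$registry_code %||% d$registry_code,
    retain_policy = decl$retain_policy %||% d$retain_policy)
  if (!meta$retain_policy %in% RETAIN_POLICIES)
    stop("invalid retain policy '", meta$retain_policy, "' for ", name,
         call. = FALSE)
  if (!is.na(meta$registry_code) && !meta$registry_code %in% REGISTRY$code)
    stop("unknown registry code '", meta$registry_code, "' for ", name,
         call. = FALSE)
  if (!is.na(meta$registry_code) && meta$hipaa_class != "direct")
    stop("registry code implies hipaa_class 'direct' for ", name, call. = FALSE)
  if (meta$hipaa_class == "direct" &&
      !meta$retain_policy %in% c("remove", "recode", "transform"))
    stop("direct identifier ", name,
         " must be removed, recoded or transformed", call. = FALSE)
  class(meta) <- "variable_meta"
  meta
}

#' Scan table cells for identifier-like values
#'
#' Tests every cell (or a subset of variables) against the registry's
#' detection pattern families — email, phone/fax, URL, IP address, SSN-like,
#' ZIP-like and ISO-date-like strings — and returns one finding per match
#' with its character span. The scanner is deterministic, read-only and
#' deliberately conservative: findings are review input, not deletions.
#'
#' @param table A data frame (one study domain).
#' @param variables Optional character vector restricting the scan to these
#'   columns (default: all columns).
#' @param families Optional subset of pattern families to apply (default:
#'   all of `names(trialdeid:::SCAN_PATTERNS)`).
#' @return Data frame with columns `variable`, `record`, `family`, `start`,
#'   `end`, `match`, `registry_code`; zero rows when nothing matches.
#' @export
scan_free_values <- function(table, variables = NULL, families = NULL) {
  stopifnot(is.data.frame(table))
  variables <- variables %||% names(table)
  families <- families %||% names(SCAN_PATTERNS)
  unknown <- setdiff(families, names(SCAN_PATTERNS))
  if (length(unknown))
    stop("unknown pattern famil(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  findings <- list()
  for (v in intersect(variables, names(table))) {
    x <- as.character(table[[v]])
    for (fam in families) {
      m <- gregexpr(SCAN_PATTERNS[[fam]], x, perl = TRUE)
      for (i in seq_along(x)) {
        if (is.na(x[i]) || m[[i]][1] == -1L) next
        starts <- as.integer(m[[i]])
        lens <- attr(m[[i]], "match.length")
        findings[[length(findings) + 1L]] <- data.frame(
          variable = v, record = i, family = fam,
          start = starts, end = starts + lens - 1L,
          match = substring(x[i], starts, starts + lens - 1L),
          registry_code = unname(SCAN_FAMILY_CODE[fam]))
      }
    }
  }
  if (!length(findings))
    return(data.frame(variable = character(), record = integer(),
                      family = character(), start = integer(),
                      end = integer(), match = character(),
                      registry_code = character()))
  out <- do.call(rbind, findings)
  out[order(out$variable, out$record, out$start, out$family), , drop = FALSE]
}

#' Scan all tables of a study
#'
#' Convenience wrapper running [scan_free_values()] over every domain.
#'
#' @param study A `trial_study`.
#' @param ... Passed to [scan_free_values()].
#' @return Data frame as in [scan_free_values()] with an extra leading
#'   `table` column.
#' @export
scan_study <- function(study, ...) {
  res <- lapply(names(study$tables), function(dom) {
    f <- scan_free_values(study$tables[[dom]], ...)
    if (nrow(f)) cbind(table = dom, f) else NULL
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    return(data.frame(table = character(), variable = character(),
                      record = integer(), family = character(),
                      start = integer(), end = integer(), match = character(),
                      registry_code = character()))
  do.call(rbind, res)
}
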