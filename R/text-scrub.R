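# Verbatim free-text handling: drop the variable, blank its values, or —
# review mode — scan and blank only the cells with identifier-like findings,
# always retaining the dictionary-coded counterpart untouched.

#' Scrub verbatim free-text variables
#'
#' For each targeted variable applies one of three policies:
#' `"drop-variable"` (the preferred default: the variable is removed),
#' `"blank-values"` (column retained, every value set to missing), or
#' `"review"` (the scanner runs on the variable and only the cells with
#' findings are blanked; the findings are returned for human review).
#' A dictionary-coded counterpart named for a target must exist and is
#' never modified — dropping verbatim text without its coded term would
#' lose the only usable information.
#'
#' @param table A data frame (one study domain).
#' @param targets Named list: variable -> `list(mode =, coded_counterpart =)`
#'   (or a mode string).
#' @return `list(table =, log =, review =)`: the scrubbed table, a log data
#'   frame of actions, and the review findings (zero rows unless mode
#'   `"review"` produced any).
#' @export
scrub_verbatim <- function(table, targets) {
  log <- empty_log()
  review <- scan_free_values(table[0, , drop = FALSE])
  for (v in names(targets)) {
    pol <- targets[[v]]
    if (is.character(pol)) pol <- list(mode = pol)
    mode <- pol$mode %||% "drop-variable"
    if (!mode %in% c("drop-variable", "blank-values", "review"))
      stop("unknown scrub mode '", mode, "' for ", v, call. = FALSE)
    if (!v %in% names(table))
      stop("scrub target '", v, "' not found in table", call. = FALSE)
    cc <- pol$coded_counterpart
    if (!is.null(cc) && !cc %in% names(table))
      stop("coded counterpart '", cc, "' for ", v,
           " is absent; refusing to scrub the only usable term", call. = FALSE)
    n <- sum(!is.na(table[[v]]))
    if (mode == "drop-variable") {
      table[[v]] <- NULL
      log <- log_append(log, NA_character_, v, "scrub.drop", "removed",
                        if (is.null(cc)) "verbatim variable removed"
                        else paste0("verbatim removed; coded term ", cc,
                                    " retained"),
                        n = n)
    } else if (mode == "blank-values") {
      table[[v]] <- rep(NA_character_, nrow(table))
      log <- log_append(log, NA_character_, v, "scrub.blank", "blanked",
                        "all values set to missing", n = n)
    } else {
      f <- scan_free_values(table, variables = v)
      if (nrow(f)) {
        table[[v]][unique(f$record)] <- NA_character_
        review <- rbind(review, f)
      }
      log <- log_append(log, NA_character_, v, "scrub.review", "blanked",
                        sprintf("review mode: %d cell(s) with findings blanked",
                                length(unique(f$record))),
                        n = length(unique(f$record)))
    }
  }
  list(table = table, log = log, review = review)
}
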