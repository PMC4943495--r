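# Consistent, content-independent random re-coding of subject and site
# identifiers. New codes are a uniformly random injection into a template
# space — never a hash of the old code, which would be dictionary-attackable
# and would make the new code depend on record content.

#' One-way fingerprint of a value
#'
#' 64-bit FNV-1a hash of the serialised value, rendered as hex. Used to
#' record the generation seed in a code key without disclosing it.
#'
#' @param x Any value; coerced via `as.character`.
#' @return A 16-character hex string.
#' @export
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\x1f"))
  # FNV-1a in two 32-bit halves to stay inside double precision
  prime <- 16777619
  h <- 2166136261
  m32 <- 2^32
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h >= 2^31) * 2^31
    h <- (h * prime) %% m32
  }
  h2 <- 2166136261
  for (b in rev(bytes)) {
    h2 <- bitwXor(as.integer(h2 %% 2^31), b) + (h2 >= 2^31) * 2^31
    h2 <- (h2 * prime) %% m32
  }
  sprintf("%04x%04x%04x%04x",
          as.integer(h %/% 65536), as.integer(h %% 65536),
          as.integer(h2 %/% 65536), as.integer(h2 %% 65536))
}

new_code_key <- function(scope, entries, seed) {
  structure(
    list(scope = scope,
         entries = entries,
         seed_fingerprint = fingerprint(c("seed", seed)),
         status = "active",
         attestation = data.frame(
           event = "created",
           n_entries = length(entries),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "code_key")
}

#' @export
print.code_key <- function(x, ...) {
  cat("<code_key> scope=", x$scope, " status=", x$status,
      " entries=", length(x$entries), "\n", sep = "")
  invisible(x)
}

# Draw a random injection old -> codes rendered from `template`, where each
# '#' is a digit position. The draw is uniform over injections, avoids any
# code already in `forbidden`, and is deterministic given the RNG state.
draw_injection <- function(old, template, forbidden = character()) {
  width <- lengths(regmatches(template, gregexpr("#", template, fixed = TRUE)))
  if (width == 0L)
    stop("code template must contain at least one '#'", call. = FALSE)
  space <- 10^width
  n <- length(old)
  if (space < n + length(forbidden))
    stop("code template space too small (", space, " codes for ", n,
         " identifiers); widen the template", call. = FALSE)
  render <- function(i) {
    digits <- formatC(i, width = width, flag = "0", format = "d")
    out <- template
    for (d in strsplit(digits, "")[[1]])
      out <- sub("#", d, out, fixed = TRUE)
    out
  }
  taken <- character(0)
  new <- character(n)
  for (j in seq_len(n)) {
    repeat {
      cand <- render(floor(stats::runif(1) * space))
      if (!cand %in% taken && !cand %in% forbidden) break
    }
    new[j] <- cand
    taken <- c(taken, cand)
  }
  stats::setNames(new, old)
}

remap_key_variable <- function(study, key_var, seed, template, prior_key,
                               scope) {
  values <- unique(stats::na.omit(unlist(
    lapply(study$tables, function(t) t[[key_var]]), use.names = FALSE)))
  if (!length(values))
    stop("no non-missing values of '", key_var, "' to remap", call. = FALSE)
  entries <- character(0)
  if (!is.null(prior_key)) {
    if (!inherits(prior_key, "code_key") || prior_key$status != "active")
      stop("prior key must be an active code_key", call. = FALSE)
    if (prior_key$scope != scope)
      stop("prior key scope '", prior_key$scope, "' does not match '",
           scope, "'", call. = FALSE)
    entries <- prior_key$entries[names(prior_key$entries) %in% values]
  }
  todo <- setdiff(values, names(entries))
  if (length(todo)) {
    fresh <- withr::with_seed(seed, {
      draw_injection(todo, template,
                     forbidden = c(values, unname(entries)))
    })
    entries <- c(entries, fresh)
  }
  for (dom in names(study$tables)) {
    col <- study$tables[[dom]][[key_var]]
    if (is.null(col)) next
    hit <- !is.na(col)
    study$tables[[dom]][[key_var]][hit] <- unname(entries[col[hit]])
  }
  list(study = study, key = new_code_key(scope, entries, seed))
}

#' Re-code subject identifiers consistently across all tables
#'
#' Replaces every occurrence of each subject code, in every domain table, by
#' the same new randomly generated code. The assignment is a uniformly
#' random injection into the template space given the seed; it carries no
#' information from the subject's records, and no new code collides with any
#' original code. Supplying a prior code key (from an earlier or extension
#' study) reuses its mappings so codes stay consistent across datasets;
#' subjects not in the prior key receive fresh codes.
#'
#' @param study A `trial_study` with `subject_key` set and no missing
#'   subject codes.
#' @param seed Integer seed (mandatory). Recorded in the key only as a
#'   one-way fingerprint.
#' @param template Code template; each `#` is a digit (default `"S#####"`).
#'   A space too small for the number of subjects is a hard error.
#' @param prior_key Optional active `code_key` of scope `"subject"`.
#' @return `list(study =, key =)` — the re-coded study and the `code_key`.
#' @export
remap_subjects <- function(study, seed, template = "S#####",
                           prior_key = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  for (dom in names(study$tables))
    if (anyNA(study$tables[[dom]][[study$subject_key]]))
      stop("missing subject codes in table '", dom, "'", call. = FALSE)
  remap_key_variable(study, study$subject_key, seed, template, prior_key,
                     scope = "subject")
}

#' Re-code site identifiers
#'
#' As [remap_subjects()], at site scope: each site code is replaced by a new
#' random code consistently wherever the site variable appears. Pooling of
#' small sites is a separate generalisation step ([pool_rare_categories()]);
#' this operation only randomises codes.
#'
#' @param study A `trial_study` with `site_key` set.
#' @param seed Integer seed.
#' @param template Code template (default `"T###"`).
#' @param prior_key Optional active `code_key` of scope `"site"`.
#' @return `list(study =, key =)`.
#' @export
remap_sites <- function(study, seed, template = "T###", prior_key = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(study$site_key))
    stop("study has no site key", call. = FALSE)
  remap_key_variable(study, study$site_key, seed, template, prior_key,
                     scope = "site")
}

#' Destroy a code key
#'
#' Erases all old-to-new mappings, marks the key destroyed and appends a
#' timestamped attestation. A destroyed key serialises without any original
#' or replacement code. Destroying an already-destroyed key is a warning
#' no-op.
#'
#' @param key A `code_key`.
#' @return The destroyed `code_key`.
#' @export
destroy_key <- function(key) {
  stopifnot(inherits(key, "code_key"))
  if (key$status == "destroyed") {
    warning("code key already destroyed; no-op", call. = FALSE)
    return(key)
  }
  key$attestation <- rbind(key$attestation, data.frame(
    event = "destroyed",
    n_entries = 0L,
    timestamp = format(Sys.time(), tz = "UTC")))
  key$entries <- stats::setNames(character(0), character(0))
  key$status <- "destroyed"
  key
}

#' Serialise a code key to JSON
#'
#' The caller designates where the serialised key lives; securing that
#' location to at least the standard applied to the original data is an
#' operational obligation of the data holder.
#'
#' @param key A `code_key`.
#' @param path Output file. The directory must exist.
#' @return `path`, invisibly.
#' @export
write_code_key <- function(key, path) {
  obj <- list(scope = key$scope,
              entries = as.list(key$entries),
              seed_fingerprint = key$seed_fingerprint,
              status = key$status,
              attestation = key$attestation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
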