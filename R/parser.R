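# Token and profile parsing/validation.
#
# Token grammar: BASE("-"PARAM)?("(CC)")?
#   BASE   matched case-insensitively against the registry, canonicalized
#          upper case
#   PARAM  any non-empty string without parentheses; free text, trimmed,
#          case-preserved (compared case-insensitively after whitespace
#          normalization)
#   (CC)   clinical-reference-data flag, allowed only on GRU, HMB, DS

#' Construct a code instance
#'
#' Low-level constructor; most callers use [cc_parse_token()].
#'
#' @param id registry code id (e.g. `"DS"`).
#' @param parameter optional free-text parameter (required iff the code is
#'   parameterized).
#' @param cc logical; clinical-reference-data flag (only GRU/HMB/DS).
#' @return An object of class `cc_instance`: a list with `id`, `tier`,
#'   `parameter`, `parameter_norm` (normalized form used in comparisons)
#'   and `cc`.
#' @export
#' @examples
#' cc_instance("DS", "cancer", cc = TRUE)
cc_instance <- function(id, parameter = NULL, cc = FALSE) {
  def <- cc_definition(id)
  if (def$parameterized) {
    if (is.null(parameter) || !nzchar(trimws(parameter))) {
      cc_abort("cc_param_arity_error",
               sprintf("code %s requires a parameter ([%s])",
                       def$id, def$parameter_role),
               token = id)
    }
    parameter <- trimws(parameter)
  } else if (!is.null(parameter)) {
    cc_abort("cc_param_arity_error",
             sprintf("code %s does not take a parameter (got '%s')",
                     def$id, parameter),
             token = id)
  }
  if (cc && !def$cc_suffix_allowed) {
    cc_abort("cc_cc_not_allowed_error",
             sprintf("the (CC) flag is not allowed on %s", def$id),
             token = id)
  }
  structure(
    list(id = def$id, tier = def$tier, parameter = parameter,
         parameter_norm = if (is.null(parameter)) NULL
                          else cc_normalize_term(parameter),
         cc = isTRUE(cc)),
    class = "cc_instance"
  )
}

#' Parse one consent-code token
#'
#' @param token a token such as `"HMB(CC)"`, `"DS-CANCER(CC)"`, `"TS-24"`.
#' @param permissive logical; if `TRUE`, an unknown base code yields an
#'   opaque instance (tier `"UNKNOWN"`) instead of an error, so foreign
#'   vocabularies can be carried through unvalidated.
#' @return A `cc_instance`.
#' @export
#' @examples
#' cc_parse_token("DS-CANCER(CC)")
#' cc_parse_token("ts-24")  # base codes are case-insensitive on input
cc_parse_token <- function(token, permissive = FALSE) {
  if (length(token) != 1L || is.na(token)) {
    cc_abort("cc_syntax_error", "token must be a single string", token = token)
  }
  raw <- trimws(token)
  if (!nzchar(raw)) cc_abort("cc_syntax_error", "empty consent-code token",
                             token = token)
  body <- raw
  cc <- FALSE
  if (grepl("\\([Cc][Cc]\\)$", body)) {
    cc <- TRUE
    body <- trimws(sub("\\([Cc][Cc]\\)$", "", body))
  }
  if (grepl("[()]", body)) {
    cc_abort("cc_syntax_error",
             sprintf("malformed token '%s': unexpected parentheses", raw),
             token = token)
  }
  dash <- regexpr("-", body, fixed = TRUE)
  if (dash > 0L) {
    base <- substr(body, 1L, dash - 1L)
    param <- trimws(substring(body, dash + 1L))
    if (!nzchar(param)) {
      cc_abort("cc_syntax_error",
               sprintf("malformed token '%s': empty parameter", raw),
               token = token)
    }
  } else {
    base <- body
    param <- NULL
  }
  base <- toupper(trimws(base))
  if (!nzchar(base)) {
    cc_abort("cc_syntax_error",
             sprintf("malformed token '%s': empty base code", raw),
             token = token)
  }
  cc_registry()
  if (is.null(.cc_env$defs[[base]])) {
    if (permissive) {
      return(structure(
        list(id = base, tier = "UNKNOWN", parameter = param,
             parameter_norm = if (is.null(param)) NULL
                              else cc_normalize_term(param),
             cc = cc),
        class = "cc_instance"
      ))
    }
    cc_abort("cc_unknown_code_error",
             sprintf("unknown consent code: '%s' (in token '%s')", base, raw),
             token = token)
  }
  cc_instance(base, param, cc)
}

#' Render a code instance to its canonical token spelling
#'
#' `cc_render_token(cc_parse_token(s))` is the canonical spelling of any
#' valid `s` (fixed point on canonical spellings).
#'
#' @param instance a `cc_instance`.
#' @return character scalar.
#' @export
#' @examples
#' cc_render_token(cc_instance("DS", "CANCER", cc = TRUE))
cc_render_token <- function(instance) {
  stopifnot(inherits(instance, "cc_instance"))
  paste0(instance$id,
         if (!is.null(instance$parameter)) paste0("-", instance$parameter),
         if (isTRUE(instance$cc)) "(CC)")
}

#' @export
print.cc_instance <- function(x, ...) {
  cat("<consent code> ", cc_render_token(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.cc_instance <- function(x, ...) cc_render_token(x)

new_profile <- function(instances, resource_kind, is_genetic_resource,
                        approved_entities) {
  tiers <- vapply(instances, function(i) i$tier, character(1))
  structure(
    list(
      primary = if (sum(tiers == "PRIMARY") == 1L) {
        instances[[which(tiers == "PRIMARY")]]
      } else NULL,
      primaries = instances[tiers == "PRIMARY"],
      secondaries = instances[tiers == "SECONDARY"],
      requirements = instances[tiers %in% c("REQUIREMENT", "PERMISSION")],
      unknown = instances[tiers == "UNKNOWN"],
      resource_kind = resource_kind,
      is_genetic_resource = isTRUE(is_genetic_resource),
      approved_entities = approved_entities
    ),
    class = "cc_profile"
  )
}

#' Parse a consent profile from tokens
#'
#' Assembles and validates the full set of consent-code tokens attached to
#' one dataset or biospecimen collection. A profile has exactly one primary
#' category ("pick only one"); secondary categories and
#' requirement/permission codes are conjunctive extra conditions.
#'
#' @param tokens character vector of code tokens.
#' @param resource_kind subset of `c("data", "biospecimen")`.
#' @param is_genetic_resource logical; gates the GSO code.
#' @param approved_entities optional named list with elements `users`,
#'   `projects`, `institutions` (identifier vectors) backing the US/PS/IS
#'   requirement codes.
#' @param permissive logical; carry unknown codes opaquely (as warnings)
#'   instead of erroring.
#' @param allow_nres_companions logical; by default a profile whose primary
#'   is NRES (no restrictions at all) may not carry companion codes. Set
#'   `TRUE` to downgrade that rule to a warning.
#' @param validate logical; if `TRUE` (default) an invalid profile raises a
#'   `cc_profile_error` condition carrying the [cc_validate_profile()]
#'   report in its `report` field.
#' @return A `cc_profile` object.
#' @export
#' @examples
#' cc_parse_profile(c("HMB(CC)", "HPOA", "PUB"),
#'                  resource_kind = "data", is_genetic_resource = TRUE)
cc_parse_profile <- function(tokens,
                             resource_kind = c("data", "biospecimen"),
                             is_genetic_resource = FALSE,
                             approved_entities = NULL,
                             permissive = FALSE,
                             allow_nres_companions = FALSE,
                             validate = TRUE) {
  if (length(tokens) == 0L) {
    cc_abort("cc_syntax_error", "a profile needs at least one code token")
  }
  resource_kind <- match.arg(resource_kind, c("data", "biospecimen"),
                             several.ok = TRUE)
  instances <- lapply(tokens, cc_parse_token, permissive = permissive)
  profile <- new_profile(instances, resource_kind, is_genetic_resource,
                         approved_entities)
  if (validate) {
    report <- cc_validate_profile(
      profile, allow_nres_companions = allow_nres_companions)
    if (!report$valid) {
      bad <- report$violations[report$violations$severity == "error", ]
      cc_abort("cc_profile_error",
               paste0("invalid consent profile: ",
                      paste(sprintf("[%s] %s", bad$rule, bad$message),
                            collapse = "; ")),
               report = report)
    }
  }
  profile
}

#' @export
print.cc_profile <- function(x, ...) {
  all <- c(x$primaries, x$secondaries, x$requirements, x$unknown)
  cat("<consent profile> ",
      paste(vapply(all, cc_render_token, character(1)), collapse = " "),
      "\n  resource: ", paste(x$resource_kind, collapse = "+"),
      if (x$is_genetic_resource) " (genetic)", "\n", sep = "")
  invisible(x)
}

violation <- function(rule, severity, message, tokens = "") {
  list(rule = rule, severity = severity, message = message,
       tokens = paste(tokens, collapse = " "))
}

#' Validate a consent profile
#'
#' Pure structural validation: the same profile always yields the same
#' report, and problems are reported, never thrown. Rule ids are stable
#' across releases:
#'
#' * `NO_PRIMARY`, `MULTIPLE_PRIMARY` — exactly one primary category
#' * `NRES_COMPANIONS` — NRES means no restrictions at all, so companion
#'   codes are contradictory (downgradable to a warning)
#' * `HPOA_SCOPE` — HPOA attaches only to HMB or DS profiles
#' * `GSO_SCOPE` — GSO applies only to genetic research resources
#' * `BIOSPECIMEN_SCOPE` — GEN/CL apply only to biospecimen resources
#' * `APPLIES_SCOPE` — a code whose applicability (data vs biospecimen)
#'   does not intersect the resource kind
#' * `SELF_CONTRADICTION` — DS-\[X\] with NDS-\[X\]: the only permitted
#'   disease is also excluded, so the permitted set is empty
#' * `CC_RUO_REDUNDANT` (warning) — a (CC) primary combined with RUO; RUO
#'   prevails (most restrictive interpretation)
#' * `UNKNOWN_CODE` (warning) — opaque code carried in permissive mode
#' * `TS_PARAM` — TS parameter is not a positive integer month count
#' * `MOR_PARAM` (warning) — MOR parameter is not an ISO-8601 date
#'
#' @param profile a `cc_profile` (possibly structurally incomplete, e.g.
#'   with zero or two primaries, as produced with `validate = FALSE`).
#' @param allow_nres_companions logical; see [cc_parse_profile()].
#' @return An object of class `cc_validation`: list with `valid` (logical;
#'   `TRUE` iff no error-severity violations) and `violations`
#'   (data.frame: `rule`, `severity`, `message`, `tokens`).
#' @export
cc_validate_profile <- function(profile, allow_nres_companions = FALSE) {
  stopifnot(inherits(profile, "cc_profile"))
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x
  tok <- function(i) cc_render_token(i)

  n_primary <- length(profile$primaries)
  if (n_primary == 0L) {
    add(violation("NO_PRIMARY", "error",
                  "a profile must contain exactly one primary category"))
  } else if (n_primary > 1L) {
    add(violation("MULTIPLE_PRIMARY", "error",
                  "pick only one primary category",
                  vapply(profile$primaries, tok, character(1))))
  }
  companions <- c(profile$secondaries, profile$requirements, profile$unknown)
  primary <- profile$primary

  if (!is.null(primary) && primary$id == "NRES" && length(companions) > 0L) {
    add(violation("NRES_COMPANIONS",
                  if (allow_nres_companions) "warning" else "error",
                  "NRES (no restrictions at all) admits no companion codes",
                  vapply(companions, tok, character(1))))
  }
  for (s in profile$secondaries) {
    if (s$id == "HPOA" &&
        (is.null(primary) || !primary$id %in% c("HMB", "DS"))) {
      add(violation("HPOA_SCOPE", "error",
                    "HPOA applies only to HMB and DS profiles", "HPOA"))
    }
    if (s$id == "GSO" && !profile$is_genetic_resource) {
      add(violation("GSO_SCOPE", "error",
                    "GSO applies only to genetic research datasets/biospecimens",
                    "GSO"))
    }
  }
  for (i in c(profile$secondaries, profile$requirements)) {
    def <- cc_definition(i$id)
    if (def$biospecimen_only && !"biospecimen" %in% profile$resource_kind) {
      add(violation("BIOSPECIMEN_SCOPE", "error",
                    sprintf("%s applies only to biospecimens", i$id), tok(i)))
    } else if (length(intersect(def$applies_to, profile$resource_kind)) == 0L) {
      add(violation("APPLIES_SCOPE", "error",
                    sprintf("%s applies to %s resources only", i$id,
                            paste(def$applies_to, collapse = "/")),
                    tok(i)))
    }
    if (i$id == "TS") {
      months <- suppressWarnings(as.integer(i$parameter))
      if (!grepl("^[0-9]+$", i$parameter) || is.na(months) || months <= 0L) {
        add(violation("TS_PARAM", "error",
                      sprintf("TS parameter must be a positive integer month count, got '%s'",
                              i$parameter), tok(i)))
      }
    }
    if (i$id == "MOR" && is.na(suppressWarnings(as.Date(i$parameter)))) {
      add(violation("MOR_PARAM", "warning",
                    sprintf("MOR parameter '%s' is not an ISO-8601 date; the embargo can only be attested, not date-checked",
                            i$parameter), tok(i)))
    }
  }
  if (!is.null(primary) && primary$id == "DS") {
    for (s in profile$secondaries) {
      if (s$id == "NDS" &&
          identical(s$parameter_norm, primary$parameter_norm)) {
        add(violation("SELF_CONTRADICTION", "error",
                      sprintf("the only permitted disease ('%s') is also excluded by %s: the permitted set is empty",
                              primary$parameter, tok(s)),
                      c(tok(primary), tok(s))))
      }
    }
  }
  if (!is.null(primary) && isTRUE(primary$cc) &&
      any(vapply(profile$secondaries, function(s) s$id == "RUO", logical(1)))) {
    add(violation("CC_RUO_REDUNDANT", "warning",
                  "RUO excludes the clinical-reference use granted by (CC); RUO prevails",
                  c(tok(primary), "RUO")))
  }
  for (u in profile$unknown) {
    add(violation("UNKNOWN_CODE", "warning",
                  sprintf("unknown code '%s' carried opaquely; it is ignored by the decision engine",
                          u$id), tok(u)))
  }

  violations <- if (length(v) == 0L) {
    data.frame(rule = character(0), severity = character(0),
               message = character(0), tokens = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(v, function(x) {
      as.data.frame(x, stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(valid = !any(violations$severity == "error"),
         violations = violations),
    class = "cc_validation"
  )
}

#' @export
print.cc_validation <- function(x, ...) {
  cat("<profile validation> ", if (x$valid) "valid" else "INVALID", "\n",
      sep = "")
  if (nrow(x$violations)) {
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  %s [%s] %s\n", x$violations$severity[i],
                  x$violations$rule[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

# every instance in a profile, canonical order: primary, secondaries,
# requirements/permissions, unknown
profile_instances <- function(profile) {
  c(profile$primaries, profile$secondaries, profile$requirements,
    profile$unknown)
}

#' Canonical token list of a profile
#'
#' @param profile a `cc_profile`.
#' @return character vector of canonical tokens.
#' @export
cc_profile_tokens <- function(profile) {
  vapply(profile_instances(profile), cc_render_token, character(1))
}
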