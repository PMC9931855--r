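# Decision engine: evaluates an access request against a consent profile.
#
# Semantics: the primary category defines the permitted purpose region
# (NRES = everything; GRU = health + other biological + POA; HMB = health
# only; DS = health related to the named disease; POA = population
# origins/ancestry only). Secondary categories are conjunctive modifiers of
# that region (TDS/RS narrow, NDS/NMDS/GSO/RUO exclude, HPOA carves
# health-related POA analysis back into HMB/DS). Requirement codes split
# into fact gates checked against requester attributes (NPU, NCU, GS, TS,
# US, PS, IS) and attestation obligations that must be agreed to (PUB, COL,
# ROR, RTN, IRB, BEN, OS, MOR). Permission codes (CQ, CS, CR, HR, ARA, GEN,
# CL) grant extras; CL/GEN gate biospecimen intents. Everything fails
# closed.

fail_rec <- function(rule = character(0), code = character(0),
                     message = character(0)) {
  list(rule = rule, code = code, message = message)
}
fail_add <- function(f, rule, code, message) {
  list(rule = c(f$rule, rule), code = c(f$code, code),
       message = c(f$message, message))
}

#' Is the request's purpose inside the profile's permitted region?
#'
#' Applies the primary category and all secondary modifiers conjunctively.
#' All rules are checked (straight-line), so the reasons list every unmet
#' purpose rule, not just the first.
#'
#' @param primary the profile's primary `cc_instance`.
#' @param secondaries list of secondary-tier `cc_instance`s.
#' @param request a [cc_request()].
#' @param term_matcher matcher from [cc_term_matcher()] (`NULL` = exact).
#' @param hpoa_disease_scoped logical; on a DS profile, must health-related
#'   ancestry analysis under HPOA also match the DS disease? Default `TRUE`
#'   (most restrictive reading).
#' @return list with `permitted` (logical) and `reasons` (list of parallel
#'   vectors `rule`, `code`, `message`).
#' @export
cc_purpose_permitted <- function(primary, secondaries, request,
                                 term_matcher = NULL,
                                 hpoa_disease_scoped = TRUE) {
  if (is.null(term_matcher)) term_matcher <- cc_term_matcher()
  f <- fail_rec()
  pid <- primary$id
  domain <- request$purpose_domain
  has_hpoa <- FALSE
  for (s in secondaries) if (s$id == "HPOA") has_hpoa <- TRUE

  if (pid == "NRES") {
    return(list(permitted = TRUE, reasons = f))
  }
  if (pid %in% c("HMB", "DS")) {
    if (domain == "other_biological") {
      f <- fail_add(f, "PURPOSE_DOMAIN", pid,
                    sprintf("%s is limited to health/medical/biomedical purposes", pid))
    } else if (domain == "poa") {
      if (!has_hpoa) {
        f <- fail_add(f, "PURPOSE_DOMAIN", pid,
                      sprintf("%s does not include the study of population origins or ancestry", pid))
      } else if (!request$poa_health_related) {
        f <- fail_add(f, "HPOA_HEALTH", "HPOA",
                      "HPOA permits population origins/ancestry analysis ONLY as it relates to health")
      }
    }
  } else if (pid == "POA") {
    if (domain != "poa") {
      f <- fail_add(f, "PURPOSE_DOMAIN", "POA",
                    "POA is limited to the study of population origins or ancestry")
    }
  }
  # GRU: all three purpose domains are inside the region

  if (pid == "DS") {
    needs_match <- !(domain == "poa" && has_hpoa && !hpoa_disease_scoped)
    if (needs_match &&
        !term_matcher(request$disease_terms, primary$parameter)) {
      f <- fail_add(f, "DS_MATCH", cc_render_token(primary),
                    sprintf("use must be related to [%s]", primary$parameter))
    }
  }

  for (s in secondaries) {
    if (s$id == "TDS") {
      if (!term_matcher(request$therapy_terms, s$parameter)) {
        f <- fail_add(f, "TDS_MATCH", cc_render_token(s),
                      sprintf("use must be related to [%s]", s$parameter))
      }
    } else if (s$id == "RS") {
      if (!term_matcher(request$research_type_terms, s$parameter)) {
        f <- fail_add(f, "RS_MATCH", cc_render_token(s),
                      sprintf("use is limited to studies of [%s]", s$parameter))
      }
    } else if (s$id == "NDS") {
      if (term_matcher(request$disease_terms, s$parameter)) {
        f <- fail_add(f, "NDS_EXCLUDED", cc_render_token(s),
                      sprintf("use is NOT allowed for research into [%s]", s$parameter))
      }
    } else if (s$id == "GSO") {
      if (request$uses_only_nongenetic_data) {
        f <- fail_add(f, "GSO_GENETIC", "GSO",
                      "use is limited to genetic studies only")
      }
    } else if (s$id == "NMDS") {
      if (request$methods_dev == "general") {
        f <- fail_add(f, "NMDS_GENERAL", "NMDS",
                      "methods development research only within the bounds of the other data use limitations")
      }
    }
  }
  # default methods policy with NMDS absent: general methods research lies
  # outside the HMB/DS/POA purpose regions; only GRU (and NRES) admit it
  if (request$methods_dev == "general" && pid != "GRU" &&
      !any(vapply(secondaries, function(s) s$id == "NMDS", logical(1)))) {
    f <- fail_add(f, "METHODS_GENERAL", pid,
                  sprintf("general methods development research is outside the %s purpose region", pid))
  }
  list(permitted = length(f$rule) == 0L, reasons = f)
}

#' Check fact gates (NPU, NCU, GS, TS, US, PS, IS)
#'
#' @param requirements list of requirement/permission-tier `cc_instance`s.
#' @param request a [cc_request()].
#' @param region_table data.frame from [cc_region_table()] (`NULL` =
#'   packaged default).
#' @param approved_entities optional named list (`users`, `projects`,
#'   `institutions`); a missing list means a US/PS/IS gate fails with
#'   "requires named approval".
#' @return list of parallel vectors `rule`, `code`, `message`, one entry
#'   per unmet gate.
#' @export
cc_evaluate_gates <- function(requirements, request, region_table = NULL,
                              approved_entities = NULL) {
  if (is.null(region_table)) region_table <- cc_region_table()
  f <- fail_rec()
  rq <- request$requester
  id_gate <- function(f, inst, ids, given, what, rule) {
    if (is.null(ids)) {
      fail_add(f, rule, inst$id,
               sprintf("%s requires named approval and no approved %s list is attached to the resource",
                       inst$id, what))
    } else if (is.null(given) || !given %in% ids) {
      fail_add(f, rule, inst$id,
               sprintf("use is limited to approved %s", what))
    } else f
  }
  for (r in requirements) {
    switch(r$id,
      NPU = if (rq$org_type != "not_for_profit") {
        f <- fail_add(f, "NPU_ORG", "NPU",
                      "use is limited to not-for-profit organizations")
      },
      NCU = if (rq$commercial_purpose) {
        f <- fail_add(f, "NCU_COMMERCIAL", "NCU",
                      "use is limited to non-commercial uses")
      },
      GS = if (!cc_in_region(rq$geography, r$parameter, region_table)) {
        f <- fail_add(f, "GS_REGION", cc_render_token(r),
                      sprintf("use is limited to within [%s]; requester geography is %s",
                              r$parameter,
                              if (is.null(rq$geography)) "unstated"
                              else rq$geography))
      },
      TS = {
        if (!grepl("^[0-9]+$", r$parameter)) {
          cc_abort("cc_gate_error",
                   sprintf("TS parameter '%s' is not an integer month count",
                           r$parameter))
        }
        months <- as.integer(r$parameter)
        if (is.null(request$duration_months)) {
          f <- fail_add(f, "TS_DURATION", cc_render_token(r),
                        sprintf("use is approved for %d months; the request states no duration", months))
        } else if (request$duration_months > months) {
          f <- fail_add(f, "TS_DURATION", cc_render_token(r),
                        sprintf("use is approved for %d months; %d requested",
                                months, request$duration_months))
        }
      },
      US = f <- id_gate(f, r, approved_entities$users, rq$user_id,
                        "users", "US_APPROVAL"),
      PS = f <- id_gate(f, r, approved_entities$projects, rq$project_id,
                        "projects", "PS_APPROVAL"),
      IS = f <- id_gate(f, r, approved_entities$institutions,
                        rq$institution_id, "institutions", "IS_APPROVAL")
    )
  }
  f
}

#' Evaluate an access request against a consent profile
#'
#' The full decision: purpose region, fact gates, attestation obligations,
#' clinical-reference use, biospecimen intents. Fails closed: a missing
#' attestation or an unverifiable gate denies, and the denial reasons list
#' exactly what would have to change.
#'
#' @inheritParams cc_purpose_permitted
#' @param profile a validated `cc_profile`.
#' @inheritParams cc_evaluate_gates
#' @return An object of class `cc_decision`: list with `status` (`"PERMIT"`,
#'   `"PERMIT_WITH_OBLIGATIONS"` or `"DENY"`), `obligations` (canonical
#'   tokens of attached obligation codes; empty on plain PERMIT),
#'   `granted_permissions` (canonical tokens of permission codes present),
#'   `denial_reasons` (parallel vectors `rule`, `code`, `message`) and
#'   `trace` (ordered rule firings: parallel vectors `rule`, `code`,
#'   `outcome`, `message`).
#' @export
#' @examples
#' p <- cc_parse_profile(c("HMB(CC)", "PUB", "IRB"))
#' r <- cc_request("health", attestations = c(PUB = TRUE, IRB = TRUE))
#' cc_evaluate(p, r)$status
cc_evaluate <- function(profile, request, term_matcher = NULL,
                        region_table = NULL, hpoa_disease_scoped = TRUE) {
  stopifnot(inherits(profile, "cc_profile"), inherits(request, "cc_request"))
  tr <- list(rule = character(0), code = character(0),
             outcome = character(0), message = character(0))
  tadd <- function(rule, code, outcome, message) {
    tr$rule <<- c(tr$rule, rule); tr$code <<- c(tr$code, code)
    tr$outcome <<- c(tr$outcome, outcome)
    tr$message <<- c(tr$message, message)
  }
  primary <- profile$primary
  if (is.null(primary)) {
    cc_abort("cc_profile_error", "profile has no single primary category")
  }

  if (primary$id == "NRES") {
    tadd("NRES_OPEN", "NRES", "pass", "No restrictions on data use")
    return(structure(
      list(status = "PERMIT", obligations = character(0),
           granted_permissions = character(0),
           denial_reasons = fail_rec(), trace = tr),
      class = "cc_decision"))
  }

  denials <- fail_rec()
  absorb <- function(f) {
    for (k in seq_along(f$rule)) {
      tadd(f$rule[k], f$code[k], "fail", f$message[k])
    }
    list(rule = c(denials$rule, f$rule), code = c(denials$code, f$code),
         message = c(denials$message, f$message))
  }

  pp <- cc_purpose_permitted(primary, profile$secondaries, request,
                             term_matcher, hpoa_disease_scoped)
  if (pp$permitted) {
    tadd("PURPOSE_PERMITTED", cc_render_token(primary), "pass",
         "requested purpose lies within the permitted region")
  } else {
    denials <- absorb(pp$reasons)
  }

  gates <- cc_evaluate_gates(profile$requirements, request, region_table,
                             profile$approved_entities)
  if (length(gates$rule) == 0L) {
    tadd("GATES_MET", "", "pass", "all fact gates met")
  } else {
    denials <- absorb(gates)
  }

  # clinical reference use needs an effective (CC) flag: cc on the primary
  # and RUO absent (RUO prevails over (CC))
  if (request$clinical_reference_use) {
    has_ruo <- any(vapply(profile$secondaries, function(s) s$id == "RUO",
                          logical(1)))
    if (has_ruo) {
      denials <- absorb(fail_add(fail_rec(), "CLINICAL_REFERENCE", "RUO",
        "RUO: use is limited to research purposes and does not include use in clinical care as reference data"))
    } else if (!isTRUE(primary$cc)) {
      denials <- absorb(fail_add(fail_rec(), "CLINICAL_REFERENCE", primary$id,
        sprintf("clinical-reference use requires the (CC) flag on %s", primary$id)))
    } else {
      tadd("CLINICAL_REFERENCE", cc_render_token(primary), "pass",
           "(CC): research data may be used as reference data in clinical care")
    }
  }

  # attestation obligations: every obligation code attached to the profile
  # must be explicitly agreed to
  obligation_ids <- cc_obligation_codes()
  obligations <- character(0)
  att <- request$attestations
  for (r in profile$requirements) {
    if (!r$id %in% obligation_ids) next
    token <- cc_render_token(r)
    obligations <- c(obligations, token)
    given <- att[match(r$id, names(att))]
    if (!isTRUE(unname(given))) {
      denials <- absorb(fail_add(fail_rec(), "OBLIGATION_UNATTESTED", token,
        sprintf("obligation %s is not attested; attesting %s would lift this denial",
                token, r$id)))
    } else {
      tadd("OBLIGATION_ATTESTED", token, "pass",
           sprintf("obligation %s attested", token))
      if (r$id == "MOR" && !is.null(request$requester$planned_publication_date)) {
        embargo <- suppressWarnings(as.Date(r$parameter))
        if (!is.na(embargo) &&
            request$requester$planned_publication_date < embargo) {
          denials <- absorb(fail_add(fail_rec(), "MOR_DATE", token,
            sprintf("publication planned for %s but results are embargoed until %s",
                    request$requester$planned_publication_date, embargo)))
        }
      }
    }
  }

  # biospecimen intents need their permission codes
  if (length(request$biospecimen_intents)) {
    present <- vapply(profile$requirements, function(r) r$id, character(1))
    if ("derive_cell_lines" %in% request$biospecimen_intents &&
        !"CL" %in% present) {
      denials <- absorb(fail_add(fail_rec(), "INTENT_CL", "CL",
        "deriving cell-lines requires the CL permission (may produce cell-lines, including stem cells, from biospecimens)"))
    }
    if ("extract_nucleic_acids" %in% request$biospecimen_intents &&
        !"GEN" %in% present) {
      denials <- absorb(fail_add(fail_rec(), "INTENT_GEN", "GEN",
        "extracting nucleic acids requires the GEN permission (may extract DNA, RNA and micro-RNA from biospecimens)"))
    }
  }

  permissions <- character(0)
  for (r in profile$requirements) {
    if (r$id %in% cc_permission_codes()) {
      permissions <- c(permissions, cc_render_token(r))
    }
  }

  status <- if (length(denials$rule)) "DENY"
            else if (length(obligations)) "PERMIT_WITH_OBLIGATIONS"
            else "PERMIT"
  structure(
    list(status = status,
         obligations = obligations,
         granted_permissions = permissions,
         denial_reasons = denials,
         trace = tr),
    class = "cc_decision"
  )
}

#' @export
print.cc_decision <- function(x, ...) {
  cat("<decision> ", x$status, "\n", sep = "")
  if (length(x$obligations)) {
    cat("  obligations: ", paste(x$obligations, collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$granted_permissions)) {
    cat("  permissions: ", paste(x$granted_permissions, collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$denial_reasons$rule)) {
    cat("  denial reasons:\n")
    for (k in seq_along(x$denial_reasons$rule)) {
      cat(sprintf("    [%s] %s: %s\n", x$denial_reasons$rule[k],
                  x$denial_reasons$code[k], x$denial_reasons$message[k]))
    }
  }
  invisible(x)
}

#' Render a human-readable rationale for a decision
#'
#' One line per recorded rule firing, in evaluation order, citing the code
#' and its registry description; denial reasons are restated at the end.
#'
#' @param decision a `cc_decision` from [cc_evaluate()].
#' @return character vector of lines (also printed when interactive via
#'   `print`).
#' @export
cc_explain <- function(decision) {
  stopifnot(inherits(decision, "cc_decision"))
  tr <- decision$trace
  lines <- character(0)
  for (k in seq_along(tr$rule)) {
    code <- tr$code[k]
    base <- sub("[-(].*$", "", code)
    desc <- if (nzchar(base) && !is.null(.cc_env$defs[[base]])) {
      sprintf(" (%s)", cc_definition(base)$description)
    } else ""
    lines <- c(lines, sprintf("%s [%s] %s%s: %s",
                              toupper(tr$outcome[k]), tr$rule[k],
                              code, desc, tr$message[k]))
  }
  dn <- decision$denial_reasons
  for (k in seq_along(dn$rule)) {
    lines <- c(lines, sprintf("DENIED [%s] %s: %s", dn$rule[k], dn$code[k],
                              dn$message[k]))
  }
  lines <- c(lines, paste0("STATUS: ", decision$status))
  lines
}
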