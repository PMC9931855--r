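# Synthetic fixtures: canonical request/profile grids, seeded random
# generators, and an independent brute-force oracle for the decision
# engine. Everything here is a pure function of its arguments (and seed);
# no external data.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# canonical placeholder parameter for each parameter role; TS and MOR get
# machine-checkable values because their parameters are typed (months, date)
canonical_param <- function(role) {
  switch(role,
         months = "12",
         date = "2030-01-01",
         "X")
}

#' The canonical request grid
#'
#' The finite enumeration of access requests spanning every axis the
#' vocabulary constrains: purpose domain (3) x disease/term match
#' archetype (match/mismatch/none, applied to disease, therapy and
#' research-type terms against the canonical placeholder parameter `"X"`)
#' x poa_health_related (2) x methods_dev (3) x clinical_reference_use (2)
#' x uses_only_nongenetic_data (2) x requester archetype (non-profit,
#' for-profit research, for-profit commercial) x attestation archetype
#' (all-yes, all-no) = 1296 requests, each combination exactly once.
#'
#' @return list of [cc_request()] objects with attribute `"factors"` (the
#'   underlying design data.frame).
#' @export
cc_request_grid <- function() {
  design <- expand.grid(
    purpose_domain = c("health", "other_biological", "poa"),
    term_match = c("match", "mismatch", "none"),
    poa_health_related = c(TRUE, FALSE),
    methods_dev = c("none", "within_bounds", "general"),
    clinical_reference_use = c(FALSE, TRUE),
    uses_only_nongenetic_data = c(FALSE, TRUE),
    requester_archetype = c("non_profit", "for_profit_research",
                            "for_profit_commercial"),
    attestation_archetype = c("all_yes", "all_no"),
    stringsAsFactors = FALSE
  )
  all_yes <- stats::setNames(rep(TRUE, length(cc_obligation_codes())),
                             cc_obligation_codes())
  requests <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    terms <- switch(row$term_match, match = "X", mismatch = "Y",
                    none = character(0))
    requester <- switch(row$requester_archetype,
      non_profit = cc_requester("not_for_profit", FALSE, geography = "CA",
                                user_id = "U1", project_id = "P1",
                                institution_id = "I1"),
      for_profit_research = cc_requester("for_profit", FALSE,
                                         geography = "CA", user_id = "U1",
                                         project_id = "P1",
                                         institution_id = "I1"),
      for_profit_commercial = cc_requester("for_profit", TRUE,
                                           geography = "CA", user_id = "U1",
                                           project_id = "P1",
                                           institution_id = "I1"))
    cc_request(
      purpose_domain = row$purpose_domain,
      disease_terms = terms, therapy_terms = terms,
      research_type_terms = terms,
      poa_health_related = row$poa_health_related,
      methods_dev = row$methods_dev,
      clinical_reference_use = row$clinical_reference_use,
      uses_only_nongenetic_data = row$uses_only_nongenetic_data,
      requester = requester,
      attestations = if (row$attestation_archetype == "all_yes") all_yes
                     else logical(0),
      duration_months = 6L
    )
  })
  attr(requests, "factors") <- design
  requests
}

secondary_candidates <- function(primary_id, is_genetic_resource) {
  ids <- c("TDS", "RS", "NDS", "HPOA", "NMDS", "RUO", "GSO")
  if (!primary_id %in% c("HMB", "DS")) ids <- setdiff(ids, "HPOA")
  if (!is_genetic_resource) ids <- setdiff(ids, "GSO")
  ids
}

subsets_up_to <- function(ids, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(ids)))) {
    combos <- utils::combn(ids, size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

build_instance <- function(id, primary_id = NULL) {
  def <- cc_definition(id)
  param <- if (def$parameterized) {
    # avoid the analytically-empty DS-X + NDS-X contradiction
    if (id == "NDS" && identical(primary_id, "DS")) "Y"
    else canonical_param(def$parameter_role)
  } else NULL
  cc_instance(id, param, cc = def$cc_suffix_allowed)
}

#' Enumerate all valid profiles with bounded companion sets
#'
#' Canonical placeholder parameters are used throughout (`"X"`, with
#' months `"12"` and date `"2030-01-01"`; NDS under a DS primary gets
#' `"Y"` so the profile is not self-contradictory). Primaries that admit
#' the (CC) flag carry it, matching their canonical table spelling.
#'
#' @param max_secondaries,max_requirements non-negative bounds on companion
#'   set sizes.
#' @param resource_kind,is_genetic_resource resource description shared by
#'   all emitted profiles.
#' @return list of validated `cc_profile`s, deduplicated, in deterministic
#'   order.
#' @export
#' @examples
#' length(cc_enumerate_profiles(0, 0))  # the five primaries
cc_enumerate_profiles <- function(max_secondaries = 1,
                                  max_requirements = 1,
                                  resource_kind = c("data", "biospecimen"),
                                  is_genetic_resource = TRUE) {
  stopifnot(max_secondaries >= 0, max_requirements >= 0)
  req_ids <- cc_codes(tier = c("REQUIREMENT", "PERMISSION"))$id
  if (!"biospecimen" %in% resource_kind) {
    req_ids <- setdiff(req_ids, c("GEN", "CL"))
  }
  profiles <- list()
  seen <- character(0)
  for (pid in cc_codes(tier = "PRIMARY")$id) {
    primary <- build_instance(pid)
    sec_sets <- if (pid == "NRES") list(character(0))
                else subsets_up_to(secondary_candidates(pid,
                                     is_genetic_resource), max_secondaries)
    req_sets <- if (pid == "NRES") list(character(0))
                else subsets_up_to(req_ids, max_requirements)
    for (secs in sec_sets) {
      for (reqs in req_sets) {
        instances <- c(list(primary),
                       lapply(secs, build_instance, primary_id = pid),
                       lapply(reqs, build_instance, primary_id = pid))
        profile <- new_profile(instances, resource_kind,
                               is_genetic_resource, NULL)
        key <- paste(sort(cc_profile_tokens(profile)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        report <- cc_validate_profile(profile)
        stopifnot(report$valid)
        profiles[[length(profiles) + 1L]] <- profile
      }
    }
  }
  profiles
}

#' The canonical engine/oracle equivalence grid of profiles
#'
#' Union of all valid profiles with at most one secondary (no
#' requirements) and at most one requirement (no secondaries):
#' every primary/modifier pair and every primary/requirement pair appears,
#' and crossing it with the 1296-point [cc_request_grid()] yields roughly
#' 1.5e5 evaluation cases. Secondary x requirement interactions are
#' exercised separately by seeded random profiles.
#'
#' @return list of `cc_profile`s.
#' @export
cc_equivalence_profiles <- function() {
  a <- cc_enumerate_profiles(1, 0)
  b <- cc_enumerate_profiles(0, 1)
  keys <- vapply(c(a, b), function(p) {
    paste(sort(cc_profile_tokens(p)), collapse = "|")
  }, character(1))
  c(a, b)[!duplicated(keys)]
}

#' Draw a random valid consent profile
#'
#' Pure function of the seed: the same seed always yields the identical
#' profile, and the caller's RNG state is untouched.
#'
#' @param seed integer seed.
#' @param constraints optional list: `primary` (a primary code id) forces
#'   the primary; `max_secondaries`/`max_requirements` bound companion
#'   counts (defaults 2); `with_entities` (logical) forces approved-entity
#'   lists on/off.
#' @return a validated `cc_profile`.
#' @export
#' @examples
#' cc_profile_tokens(cc_random_profile(42))
cc_random_profile <- function(seed, constraints = list()) {
  with_seed(seed, {
    primaries <- cc_codes(tier = "PRIMARY")$id
    pid <- constraints$primary %||% sample(primaries, 1L)
    if (!pid %in% primaries) {
      cc_abort("cc_unknown_code_error",
               sprintf("constraint primary '%s' is not a primary code", pid))
    }
    if (pid == "NRES") {
      return(cc_parse_profile("NRES", is_genetic_resource = TRUE))
    }
    max_sec <- constraints$max_secondaries %||% 2L
    max_req <- constraints$max_requirements %||% 2L
    diseases <- c("CANCER", "HIV", "ALS", "DIABETES")
    param_for <- function(id) {
      def <- cc_definition(id)
      if (!def$parameterized) return(NULL)
      switch(def$parameter_role,
             disease = sample(diseases, 1L),
             therapy_or_drug = sample(c("RITUXIMAB", "STATINS"), 1L),
             research_type = sample(c("PEDIATRIC", "AGING"), 1L),
             geographic_region = sample(c("EU", "NORTH_AMERICA", "AFRICA"),
                                        1L),
             months = sample(c("6", "12", "24"), 1L),
             date = sample(c("2026-01-01", "2030-06-30"), 1L),
             "X")
    }
    primary <- cc_instance(pid, param_for(pid),
                           cc = cc_definition(pid)$cc_suffix_allowed &&
                                sample(c(TRUE, FALSE), 1L))
    sec_ids <- secondary_candidates(pid, is_genetic_resource = TRUE)
    secs <- sample(sec_ids, sample(0:min(max_sec, length(sec_ids)), 1L))
    req_ids <- cc_codes(tier = c("REQUIREMENT", "PERMISSION"))$id
    reqs <- sample(req_ids, sample(0:min(max_req, length(req_ids)), 1L))
    make <- function(id) {
      param <- param_for(id)
      # a DS profile must not exclude its own disease
      if (id == "NDS" && pid == "DS") {
        param <- sample(setdiff(diseases, primary$parameter), 1L)
      }
      cc_instance(id, param)
    }
    entities <- if (isTRUE(constraints$with_entities) ||
                    (is.null(constraints$with_entities) &&
                     sample(c(TRUE, FALSE), 1L))) {
      list(users = c("U1", "U2"), projects = "P1", institutions = "I1")
    } else NULL
    profile <- new_profile(
      c(list(primary), lapply(secs, make), lapply(reqs, make)),
      resource_kind = c("data", "biospecimen"),
      is_genetic_resource = TRUE,
      approved_entities = entities
    )
    report <- cc_validate_profile(profile)
    stopifnot(report$valid)
    profile
  })
}

#' Draw a random well-formed access request
#'
#' Pure function of the seed.
#'
#' @param seed integer seed.
#' @return a [cc_request()].
#' @export
cc_random_request <- function(seed) {
  with_seed(seed, {
    term_pool <- c("CANCER", "HIV", "ALS", "DIABETES", "X", "Y")
    pick_terms <- function() sample(term_pool, sample(0:2, 1L))
    requester <- cc_requester(
      org_type = sample(c("not_for_profit", "for_profit"), 1L),
      commercial_purpose = sample(c(TRUE, FALSE), 1L),
      geography = sample(c("FR", "US", "ZA", "CA", "JP"), 1L),
      user_id = sample(c("U1", "U9"), 1L),
      project_id = sample(c("P1", "P9"), 1L),
      institution_id = sample(c("I1", "I9"), 1L),
      planned_publication_date = sample(list(NULL, "2026-06-30",
                                             "2031-01-01"), 1L)[[1]]
    )
    atts <- stats::setNames(sample(c(TRUE, FALSE), 8, replace = TRUE),
                            cc_obligation_codes())
    cc_request(
      purpose_domain = sample(c("health", "other_biological", "poa"), 1L),
      disease_terms = pick_terms(),
      therapy_terms = sample(c("RITUXIMAB", "STATINS", "X"),
                             sample(0:1, 1L)),
      research_type_terms = sample(c("PEDIATRIC", "AGING", "X"),
                                   sample(0:1, 1L)),
      poa_health_related = sample(c(TRUE, FALSE), 1L),
      methods_dev = sample(c("none", "within_bounds", "general"), 1L),
      clinical_reference_use = sample(c(TRUE, FALSE), 1L),
      uses_only_nongenetic_data = sample(c(TRUE, FALSE), 1L),
      requester = requester,
      attestations = atts,
      biospecimen_intents = sample(c("derive_cell_lines",
                                     "extract_nucleic_acids"),
                                   sample(0:2, 1L)),
      duration_months = sample(list(NULL, 6L, 12L, 36L), 1L)[[1]]
    )
  })
}

#' Comparison key of a decision
#'
#' `status | sorted obligations | sorted denial rule ids` — the tuple on
#' which the engine and the brute-force oracle must agree.
#'
#' @param decision a `cc_decision` or an oracle decision.
#' @return character scalar.
#' @export
cc_decision_key <- function(decision) {
  rules <- if (inherits(decision, "cc_decision")) {
    decision$denial_reasons$rule
  } else decision$denial_rules
  paste(decision$status,
        paste(sort(decision$obligations), collapse = ","),
        paste(sort(rules), collapse = ","),
        sep = " | ")
}

#' Brute-force reference decision (the oracle)
#'
#' A deliberately naive, straight-line re-statement of the vocabulary's
#' semantics: one conditional per code, no shared helpers with the decision
#' engine, exact normalized term equality only. Exists solely so that
#' [cc_evaluate()] can be checked against an independent implementation on
#' exhaustive grids.
#'
#' @param profile a validated `cc_profile`.
#' @param request a [cc_request()].
#' @param region_table optional region membership data.frame.
#' @return list with `status`, `obligations` (canonical tokens) and
#'   `denial_rules` (rule ids, one per failed rule).
#' @export
cc_oracle_evaluate <- function(profile, request, region_table = NULL) {
  up <- function(x) toupper(gsub("[[:space:]]+", " ", trimws(x)))
  deny <- character(0)
  pri <- profile$primary
  secs <- profile$secondaries
  reqs <- profile$requirements

  if (pri$id == "NRES") {
    return(list(status = "PERMIT", obligations = character(0),
                denial_rules = character(0)))
  }

  sec_ids <- vapply(secs, function(s) s$id, character(1))
  domain <- request$purpose_domain
  dis <- up(request$disease_terms)

  # --- purpose region of the primary ---
  if (pri$id == "HMB") {
    if (domain == "other_biological") deny <- c(deny, "PURPOSE_DOMAIN")
    if (domain == "poa" && !("HPOA" %in% sec_ids)) {
      deny <- c(deny, "PURPOSE_DOMAIN")
    }
    if (domain == "poa" && "HPOA" %in% sec_ids &&
        !request$poa_health_related) {
      deny <- c(deny, "HPOA_HEALTH")
    }
  }
  if (pri$id == "DS") {
    if (domain == "other_biological") deny <- c(deny, "PURPOSE_DOMAIN")
    if (domain == "poa" && !("HPOA" %in% sec_ids)) {
      deny <- c(deny, "PURPOSE_DOMAIN")
    }
    if (domain == "poa" && "HPOA" %in% sec_ids &&
        !request$poa_health_related) {
      deny <- c(deny, "HPOA_HEALTH")
    }
    if (!(up(pri$parameter) %in% dis)) deny <- c(deny, "DS_MATCH")
  }
  if (pri$id == "POA" && domain != "poa") {
    deny <- c(deny, "PURPOSE_DOMAIN")
  }
  # GRU: every domain permitted

  # --- secondary modifiers, one literal branch per code ---
  for (s in secs) {
    if (s$id == "TDS" &&
        !(up(s$parameter) %in% up(request$therapy_terms))) {
      deny <- c(deny, "TDS_MATCH")
    }
    if (s$id == "RS" &&
        !(up(s$parameter) %in% up(request$research_type_terms))) {
      deny <- c(deny, "RS_MATCH")
    }
    if (s$id == "NDS" && up(s$parameter) %in% dis) {
      deny <- c(deny, "NDS_EXCLUDED")
    }
    if (s$id == "GSO" && request$uses_only_nongenetic_data) {
      deny <- c(deny, "GSO_GENETIC")
    }
    if (s$id == "NMDS" && request$methods_dev == "general") {
      deny <- c(deny, "NMDS_GENERAL")
    }
  }
  if (request$methods_dev == "general" && !("NMDS" %in% sec_ids) &&
      pri$id != "GRU") {
    deny <- c(deny, "METHODS_GENERAL")
  }

  # --- fact gates ---
  for (r in reqs) {
    if (r$id == "NPU" && request$requester$org_type == "for_profit") {
      deny <- c(deny, "NPU_ORG")
    }
    if (r$id == "NCU" && request$requester$commercial_purpose) {
      deny <- c(deny, "NCU_COMMERCIAL")
    }
    if (r$id == "GS") {
      geo <- request$requester$geography
      inside <- FALSE
      if (!is.null(geo) && nzchar(geo)) {
        if (up(geo) == up(r$parameter)) inside <- TRUE
        if (!is.null(region_table) &&
            up(geo) %in% region_table$member[region_table$region ==
                                             up(r$parameter)]) {
          inside <- TRUE
        }
      }
      if (!inside) deny <- c(deny, "GS_REGION")
    }
    if (r$id == "TS") {
      months <- as.integer(r$parameter)
      if (is.null(request$duration_months) ||
          request$duration_months > months) {
        deny <- c(deny, "TS_DURATION")
      }
    }
    if (r$id == "US") {
      ok <- !is.null(profile$approved_entities$users) &&
            !is.null(request$requester$user_id) &&
            request$requester$user_id %in% profile$approved_entities$users
      if (!ok) deny <- c(deny, "US_APPROVAL")
    }
    if (r$id == "PS") {
      ok <- !is.null(profile$approved_entities$projects) &&
            !is.null(request$requester$project_id) &&
            request$requester$project_id %in%
              profile$approved_entities$projects
      if (!ok) deny <- c(deny, "PS_APPROVAL")
    }
    if (r$id == "IS") {
      ok <- !is.null(profile$approved_entities$institutions) &&
            !is.null(request$requester$institution_id) &&
            request$requester$institution_id %in%
              profile$approved_entities$institutions
      if (!ok) deny <- c(deny, "IS_APPROVAL")
    }
  }

  # --- clinical reference use ---
  if (request$clinical_reference_use) {
    if ("RUO" %in% sec_ids || !isTRUE(pri$cc)) {
      deny <- c(deny, "CLINICAL_REFERENCE")
    }
  }

  # --- attestation obligations ---
  obligations <- character(0)
  for (r in reqs) {
    if (r$id %in% c("PUB", "COL", "ROR", "RTN", "IRB", "BEN", "OS", "MOR")) {
      token <- paste0(r$id,
                      if (!is.null(r$parameter)) paste0("-", r$parameter))
      obligations <- c(obligations, token)
      given <- request$attestations[match(r$id, names(request$attestations))]
      if (!identical(unname(given), TRUE)) {
        deny <- c(deny, "OBLIGATION_UNATTESTED")
      } else if (r$id == "MOR" &&
                 !is.null(request$requester$planned_publication_date)) {
        embargo <- suppressWarnings(as.Date(r$parameter))
        if (!is.na(embargo) &&
            request$requester$planned_publication_date < embargo) {
          deny <- c(deny, "MOR_DATE")
        }
      }
    }
  }

  # --- biospecimen intents ---
  req_ids <- vapply(reqs, function(r) r$id, character(1))
  if ("derive_cell_lines" %in% request$biospecimen_intents &&
      !("CL" %in% req_ids)) {
    deny <- c(deny, "INTENT_CL")
  }
  if ("extract_nucleic_acids" %in% request$biospecimen_intents &&
      !("GEN" %in% req_ids)) {
    deny <- c(deny, "INTENT_GEN")
  }

  status <- if (length(deny) > 0L) "DENY"
            else if (length(obligations) > 0L) "PERMIT_WITH_OBLIGATIONS"
            else "PERMIT"
  list(status = status, obligations = obligations, denial_rules = deny)
}

#' Emit a reproducible fixture catalog and request set
#'
#' @param seed integer seed.
#' @param n_profiles,n_requests counts.
#' @return list with `catalog` (list of `cc_catalog_entry`) and `requests`
#'   (list of [cc_request()]).
#' @export
cc_emit_fixtures <- function(seed, n_profiles = 20, n_requests = 5) {
  catalog <- lapply(seq_len(n_profiles), function(i) {
    profile <- cc_random_profile(seed * 1000L + i)
    cc_catalog_entry(
      dataset_id = sprintf("DS%04d", i),
      title = sprintf("synthetic dataset %d", i),
      profile_tokens = cc_profile_tokens(profile),
      resource_kind = profile$resource_kind,
      is_genetic_resource = profile$is_genetic_resource,
      approved_entities = profile$approved_entities
    )
  })
  requests <- lapply(seq_len(n_requests), function(i) {
    cc_random_request(seed * 2000L + i)
  })
  list(catalog = catalog, requests = requests)
}
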