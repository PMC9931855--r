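# Dataset catalog I/O and filtering.
#
# Canonical exchange format is JSON (reference schemas under inst/schema/);
# TSV is supported for spreadsheet-based curation, with profile_tokens and
# resource_kind as comma-separated strings (approved_entities is JSON-only).

#' Construct a catalog entry
#'
#' @param dataset_id unique identifier within a catalog.
#' @param title free text.
#' @param profile_tokens character vector of consent-code tokens.
#' @param resource_kind subset of `c("data", "biospecimen")`.
#' @param is_genetic_resource logical.
#' @param approved_entities optional named list (`users`, `projects`,
#'   `institutions`).
#' @return An object of class `cc_catalog_entry`; the profile is parsed and
#'   validated eagerly.
#' @export
cc_catalog_entry <- function(dataset_id, title = "", profile_tokens,
                             resource_kind = c("data", "biospecimen"),
                             is_genetic_resource = FALSE,
                             approved_entities = NULL) {
  profile <- cc_parse_profile(profile_tokens,
                              resource_kind = resource_kind,
                              is_genetic_resource = is_genetic_resource,
                              approved_entities = approved_entities)
  structure(
    list(dataset_id = as.character(dataset_id), title = as.character(title),
         resource_kind = profile$resource_kind,
         is_genetic_resource = profile$is_genetic_resource,
         profile_tokens = cc_profile_tokens(profile),
         approved_entities = approved_entities,
         profile = profile),
    class = "cc_catalog_entry"
  )
}

entry_from_record <- function(rec) {
  if (is.null(rec$dataset_id) || !nzchar(rec$dataset_id)) {
    cc_abort("cc_schema_error", "catalog entry is missing dataset_id")
  }
  tryCatch(
    cc_catalog_entry(
      dataset_id = rec$dataset_id,
      title = if (is.null(rec$title)) "" else rec$title,
      profile_tokens = unlist(rec$profile_tokens),
      resource_kind = unlist(rec$resource_kind),
      is_genetic_resource = isTRUE(rec$is_genetic_resource),
      approved_entities = rec$approved_entities
    ),
    cc_error = function(e) {
      cc_abort("cc_schema_error",
               sprintf("dataset '%s': %s", rec$dataset_id,
                       conditionMessage(e)),
               dataset_id = rec$dataset_id)
    }
  )
}

#' Read a dataset catalog (JSON or TSV)
#'
#' @param path file path; dialect inferred from the extension (`.json` vs
#'   `.tsv`/`.txt`) unless `format` is given.
#' @param strictness `"strict"` aborts on the first invalid entry;
#'   `"lenient"` skips invalid entries with a warning.
#' @param format `"json"`, `"tsv"` or `NULL` (infer).
#' @return list of `cc_catalog_entry` (class `cc_catalog`), in file order.
#' @export
cc_read_catalog <- function(path, strictness = c("strict", "lenient"),
                            format = NULL) {
  strictness <- match.arg(strictness)
  if (!file.exists(path)) {
    cc_abort("cc_schema_error", sprintf("no such catalog file: %s", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  records <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    tab <- utils::read.delim(path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    lapply(seq_len(nrow(tab)), function(i) {
      list(dataset_id = tab$dataset_id[i],
           title = if ("title" %in% names(tab)) tab$title[i] else "",
           resource_kind = trimws(strsplit(tab$resource_kind[i], ",")[[1]]),
           is_genetic_resource =
             toupper(tab$is_genetic_resource[i]) %in% c("TRUE", "1", "YES"),
           profile_tokens = trimws(strsplit(tab$profile_tokens[i], ",")[[1]]),
           approved_entities = NULL)
    })
  }
  entries <- list()
  for (rec in records) {
    e <- tryCatch(entry_from_record(rec), cc_schema_error = function(err) err)
    if (inherits(e, "cc_schema_error")) {
      if (strictness == "strict") stop(e)
      warning(sprintf("skipping invalid catalog entry: %s",
                      conditionMessage(e)), call. = FALSE)
    } else {
      entries[[length(entries) + 1L]] <- e
    }
  }
  ids <- vapply(entries, function(e) e$dataset_id, character(1))
  if (anyDuplicated(ids)) {
    cc_abort("cc_schema_error",
             sprintf("duplicate dataset_id in catalog: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(entries, class = "cc_catalog")
}

#' Write a dataset catalog as JSON
#'
#' @param catalog a `cc_catalog` or list of `cc_catalog_entry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
cc_write_catalog <- function(catalog, path) {
  records <- lapply(catalog, function(e) {
    rec <- list(dataset_id = e$dataset_id, title = e$title,
                resource_kind = as.list(e$resource_kind),
                is_genetic_resource = e$is_genetic_resource,
                profile_tokens = as.list(e$profile_tokens))
    if (!is.null(e$approved_entities)) {
      rec$approved_entities <- lapply(e$approved_entities, as.list)
    }
    rec
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Evaluate one request against every catalog entry
#'
#' @param catalog from [cc_read_catalog()] (or a list of entries).
#' @param request a [cc_request()].
#' @param term_matcher,region_table,hpoa_disease_scoped passed to
#'   [cc_evaluate()].
#' @return An object of class `cc_decision_set`: list with `decisions`
#'   (named list of `cc_decision`, sorted by dataset_id) and `summary`
#'   (named integer counts by status). Output is invariant to catalog
#'   entry order.
#' @export
cc_filter_catalog <- function(catalog, request, term_matcher = NULL,
                              region_table = NULL,
                              hpoa_disease_scoped = TRUE) {
  ids <- vapply(catalog, function(e) e$dataset_id, character(1))
  ord <- order(ids, method = "radix")
  decisions <- lapply(catalog[ord], function(e) {
    cc_evaluate(e$profile, request, term_matcher, region_table,
                hpoa_disease_scoped)
  })
  names(decisions) <- ids[ord]
  statuses <- vapply(decisions, function(d) d$status, character(1))
  summary <- vapply(c("PERMIT", "PERMIT_WITH_OBLIGATIONS", "DENY"),
                    function(s) sum(statuses == s), integer(1))
  structure(list(decisions = decisions, summary = summary),
            class = "cc_decision_set")
}

#' @export
print.cc_decision_set <- function(x, ...) {
  cat("<decision set> ", length(x$decisions), " entries: ",
      paste(sprintf("%s=%d", names(x$summary), x$summary), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

decision_record <- function(id, d) {
  list(dataset_id = id, status = d$status,
       obligations = paste(d$obligations, collapse = ";"),
       denial_reasons = paste(
         sprintf("%s:%s", d$denial_reasons$rule, d$denial_reasons$code),
         collapse = ";"))
}

#' Write decisions to JSON or TSV
#'
#' Stable columns: `dataset_id`, `status`, `obligations` (semicolon-joined
#' canonical tokens), `denial_reasons` (semicolon-joined `rule:code`).
#'
#' @param decisions a `cc_decision_set` from [cc_filter_catalog()] (or its
#'   `decisions` element).
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
cc_write_decisions <- function(decisions, path,
                               format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(decisions, "cc_decision_set")) {
    decisions <- decisions$decisions
  }
  recs <- lapply(names(decisions), function(id) {
    decision_record(id, decisions[[id]])
  })
  if (format == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    tab <- if (length(recs)) {
      do.call(rbind, lapply(recs, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(dataset_id = character(0), status = character(0),
                 obligations = character(0), denial_reasons = character(0),
                 stringsAsFactors = FALSE)
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back a decisions file written by [cc_write_decisions()]
#'
#' @param path file path.
#' @param format `"json"`, `"tsv"` or `NULL` (infer from extension).
#' @return data.frame with the stable columns.
#' @export
cc_read_decisions <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0L) {
      return(data.frame(dataset_id = character(0), status = character(0),
                        obligations = character(0),
                        denial_reasons = character(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(recs, function(r) {
      data.frame(dataset_id = r$dataset_id, status = r$status,
                 obligations = r$obligations,
                 denial_reasons = r$denial_reasons,
                 stringsAsFactors = FALSE)
    }))
  } else {
    utils::read.delim(path, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, colClasses = "character")
  }
}

#' Build an access request from its JSON representation
#'
#' The JSON schema mirrors [cc_request()]; see
#' `inst/schema/request.schema.json`.
#'
#' @param x a file path or a parsed list.
#' @return a [cc_request()].
#' @export
cc_request_from_json <- function(x) {
  rec <- if (is.character(x)) jsonlite::fromJSON(x, simplifyVector = FALSE)
         else x
  rq <- rec$requester
  requester <- cc_requester(
    org_type = if (is.null(rq$org_type)) "not_for_profit" else rq$org_type,
    commercial_purpose = isTRUE(rq$commercial_purpose),
    geography = rq$geography,
    user_id = rq$user_id, project_id = rq$project_id,
    institution_id = rq$institution_id,
    planned_publication_date = rq$planned_publication_date
  )
  att <- unlist(rec$attestations)
  cc_request(
    purpose_domain = rec$purpose_domain,
    disease_terms = unlist(rec$disease_terms),
    therapy_terms = unlist(rec$therapy_terms),
    research_type_terms = unlist(rec$research_type_terms),
    poa_health_related = isTRUE(rec$poa_health_related),
    methods_dev = if (is.null(rec$methods_dev)) "none" else rec$methods_dev,
    clinical_reference_use = isTRUE(rec$clinical_reference_use),
    uses_only_nongenetic_data = isTRUE(rec$uses_only_nongenetic_data),
    requester = requester,
    attestations = if (is.null(att)) logical(0) else att,
    biospecimen_intents = unlist(rec$biospecimen_intents),
    duration_months = rec$duration_months
  )
}

#' Build a consent profile from its JSON representation
#'
#' Format: `{"codes": [...], "resource_kind": [...],
#' "is_genetic_resource": bool, "approved_entities": {...}}`.
#'
#' @param x a file path or a parsed list.
#' @return a `cc_profile`.
#' @export
cc_profile_from_json <- function(x) {
  rec <- if (is.character(x)) jsonlite::fromJSON(x, simplifyVector = FALSE)
         else x
  cc_parse_profile(
    tokens = unlist(rec$codes),
    resource_kind = if (is.null(rec$resource_kind)) c("data", "biospecimen")
                    else unlist(rec$resource_kind),
    is_genetic_resource = isTRUE(rec$is_genetic_resource),
    approved_entities = lapply(rec$approved_entities, unlist)
  )
}

#' Serialize an access request to a plain list (for JSON export)
#'
#' Inverse of [cc_request_from_json()]: `cc_request_from_json` applied to
#' the result reconstructs an equivalent request.
#'
#' @param request a [cc_request()].
#' @return a list mirroring the request JSON schema.
#' @export
cc_request_to_list <- function(request) {
  stopifnot(inherits(request, "cc_request"))
  rq <- request$requester
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  out <- list(
    purpose_domain = request$purpose_domain,
    disease_terms = as.list(request$disease_terms),
    therapy_terms = as.list(request$therapy_terms),
    research_type_terms = as.list(request$research_type_terms),
    poa_health_related = request$poa_health_related,
    methods_dev = request$methods_dev,
    clinical_reference_use = request$clinical_reference_use,
    uses_only_nongenetic_data = request$uses_only_nongenetic_data,
    requester = drop_null(list(
      org_type = rq$org_type,
      commercial_purpose = rq$commercial_purpose,
      geography = rq$geography,
      user_id = rq$user_id, project_id = rq$project_id,
      institution_id = rq$institution_id,
      planned_publication_date =
        if (is.null(rq$planned_publication_date)) NULL
        else format(rq$planned_publication_date)
    )),
    attestations = as.list(request$attestations),
    biospecimen_intents = as.list(request$biospecimen_intents)
  )
  if (!is.null(request$duration_months)) {
    out$duration_months <- request$duration_months
  }
  out
}

#' Serialize a decision to a plain list (for JSON export)
#'
#' @param decision a `cc_decision`.
#' @return a list with stable field names and rule ids.
#' @export
cc_decision_to_list <- function(decision) {
  list(
    status = decision$status,
    obligations = as.list(decision$obligations),
    granted_permissions = as.list(decision$granted_permissions),
    denial_reasons = lapply(seq_along(decision$denial_reasons$rule),
      function(k) list(rule = decision$denial_reasons$rule[k],
                       code = decision$denial_reasons$code[k],
                       message = decision$denial_reasons$message[k])),
    trace = lapply(seq_along(decision$trace$rule),
      function(k) list(rule = decision$trace$rule[k],
                       code = decision$trace$code[k],
                       outcome = decision$trace$outcome[k],
                       message = decision$trace$message[k]))
  )
}
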