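# Structured access requests.

#' Requester attributes
#'
#' @param org_type `"for_profit"` or `"not_for_profit"`.
#' @param commercial_purpose logical; is the intended use itself commercial
#'   (NCU constrains the use type; NPU constrains the organization type —
#'   a not-for-profit commercial use fails NCU but passes NPU).
#' @param geography country/region label (ISO-3166 alpha-2 codes work with
#'   the packaged region table).
#' @param user_id,project_id,institution_id optional identifiers checked
#'   against a profile's approved-entity lists (US/PS/IS codes).
#' @param planned_publication_date optional ISO-8601 date, cross-checked
#'   against a MOR embargo when provided.
#' @return An object of class `cc_requester`.
#' @export
#' @examples
#' cc_requester("not_for_profit", geography = "FR")
cc_requester <- function(org_type = c("not_for_profit", "for_profit"),
                         commercial_purpose = FALSE,
                         geography = NULL,
                         user_id = NULL, project_id = NULL,
                         institution_id = NULL,
                         planned_publication_date = NULL) {
  org_type <- match.arg(org_type)
  if (!is.null(planned_publication_date)) {
    d <- suppressWarnings(as.Date(planned_publication_date))
    if (is.na(d)) {
      cc_abort("cc_schema_error",
               sprintf("planned_publication_date '%s' is not an ISO-8601 date",
                       planned_publication_date))
    }
    planned_publication_date <- d
  }
  structure(
    list(org_type = org_type,
         commercial_purpose = isTRUE(commercial_purpose),
         geography = geography,
         user_id = user_id, project_id = project_id,
         institution_id = institution_id,
         planned_publication_date = planned_publication_date),
    class = "cc_requester"
  )
}

#' Structured research-use request
#'
#' Describes a proposed use of a dataset or biospecimen collection in the
#' axes the Consent Codes constrain.
#'
#' @param purpose_domain `"health"` (health/medical/biomedical),
#'   `"other_biological"` (other biological research) or `"poa"`
#'   (population origins or ancestry research).
#' @param disease_terms character vector of disease labels the study
#'   targets (required for a match under DS, checked against NDS
#'   exclusions).
#' @param therapy_terms therapies/drugs the study relates to (TDS).
#' @param research_type_terms research types describing the study (RS).
#' @param poa_health_related logical; for `purpose_domain = "poa"`, whether
#'   the ancestry analysis is performed only as it relates to health
#'   (the HPOA carve-out within HMB/DS).
#' @param methods_dev `"none"`, `"within_bounds"` (methods development that
#'   directly supports the permitted research) or `"general"` (general
#'   methods research beyond those bounds).
#' @param clinical_reference_use logical; will the data be used as
#'   background reference data in clinical activities (the (CC) flag)?
#' @param uses_only_nongenetic_data logical; a study using only phenotype or
#'   other non-genetic data (vetoed by GSO).
#' @param requester a [cc_requester()].
#' @param attestations named logical vector/list keyed by obligation code
#'   (PUB, COL, ROR, RTN, IRB, BEN, OS, MOR); a missing attestation counts
#'   as not given (fail closed).
#' @param biospecimen_intents subset of `c("derive_cell_lines",
#'   "extract_nucleic_acids")`.
#' @param duration_months positive integer; requested duration of use
#'   (checked against TS), or `NULL` when open-ended.
#' @return An object of class `cc_request`.
#' @export
#' @examples
#' cc_request("health", disease_terms = "CANCER",
#'            requester = cc_requester("not_for_profit"),
#'            attestations = c(PUB = TRUE, IRB = TRUE))
cc_request <- function(purpose_domain = c("health", "other_biological", "poa"),
                       disease_terms = character(0),
                       therapy_terms = character(0),
                       research_type_terms = character(0),
                       poa_health_related = FALSE,
                       methods_dev = c("none", "within_bounds", "general"),
                       clinical_reference_use = FALSE,
                       uses_only_nongenetic_data = FALSE,
                       requester = cc_requester(),
                       attestations = logical(0),
                       biospecimen_intents = character(0),
                       duration_months = NULL) {
  purpose_domain <- match.arg(purpose_domain)
  methods_dev <- match.arg(methods_dev)
  stopifnot(inherits(requester, "cc_requester"))
  attestations <- unlist(attestations)
  if (length(attestations) && is.null(names(attestations))) {
    cc_abort("cc_schema_error", "attestations must be named by obligation code")
  }
  if (length(biospecimen_intents)) {
    biospecimen_intents <- match.arg(
      biospecimen_intents, c("derive_cell_lines", "extract_nucleic_acids"),
      several.ok = TRUE)
  }
  if (!is.null(duration_months)) {
    duration_months <- as.integer(duration_months)
    stopifnot(length(duration_months) == 1L, !is.na(duration_months),
              duration_months > 0L)
  }
  structure(
    list(purpose_domain = purpose_domain,
         disease_terms = as.character(disease_terms),
         therapy_terms = as.character(therapy_terms),
         research_type_terms = as.character(research_type_terms),
         poa_health_related = isTRUE(poa_health_related),
         methods_dev = methods_dev,
         clinical_reference_use = isTRUE(clinical_reference_use),
         uses_only_nongenetic_data = isTRUE(uses_only_nongenetic_data),
         requester = requester,
         attestations = stats::setNames(as.logical(attestations),
                                        names(attestations)),
         biospecimen_intents = as.character(biospecimen_intents),
         duration_months = duration_months),
    class = "cc_request"
  )
}

#' @export
print.cc_request <- function(x, ...) {
  cat("<access request> domain=", x$purpose_domain,
      if (length(x$disease_terms))
        paste0(" diseases={", paste(x$disease_terms, collapse = ", "), "}"),
      " org=", x$requester$org_type,
      if (x$requester$commercial_purpose) " (commercial)",
      "\n", sep = "")
  invisible(x)
}
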