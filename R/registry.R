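# Consent Codes v4 registry: the packaged vocabulary table and lookups.

#' The Consent Codes v4 registry
#'
#' Returns the full vocabulary table, one row per code, in canonical table
#' order (primary categories, then secondary categories, then requirements
#' and permissions). The table is shipped as a plain TSV under
#' `inst/extdata/consent_codes_v4.tsv` so that non-programmers can audit the
#' transcription; it is loaded once per session and then frozen.
#'
#' @return A data.frame with columns `id`, `name`, `tier` (one of
#'   `"PRIMARY"`, `"SECONDARY"`, `"REQUIREMENT"`, `"PERMISSION"`),
#'   `parameterized` (logical), `parameter_role`, `cc_suffix_allowed`
#'   (logical; `TRUE` only for GRU, HMB, DS), `applies_to`
#'   (`"data"`, `"biospecimen"` or `"data|biospecimen"`), `genetic_only`
#'   (logical; `TRUE` only for GSO), `biospecimen_only` (logical; `TRUE`
#'   only for GEN and CL), `version_introduced` and `description`.
#' @export
#' @examples
#' reg <- cc_registry()
#' table(reg$tier)
cc_registry <- function() {
  if (is.null(.cc_env$registry)) {
    path <- system.file("extdata", "consent_codes_v4.tsv",
                        package = "consentcodes", mustWork = TRUE)
    reg <- utils::read.delim(path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
    for (col in c("parameterized", "cc_suffix_allowed",
                  "genetic_only", "biospecimen_only")) {
      reg[[col]] <- reg[[col]] == "TRUE"
    }
    stopifnot(!anyDuplicated(reg$id),
              identical(reg$parameterized, reg$parameter_role != "none"))
    rownames(reg) <- reg$id
    .cc_env$registry <- reg
    # fast lookup list used in hot paths
    .cc_env$defs <- lapply(seq_len(nrow(reg)), function(i) {
      row <- reg[i, , drop = FALSE]
      list(
        id = row$id, name = row$name, tier = row$tier,
        parameterized = row$parameterized,
        parameter_role = row$parameter_role,
        cc_suffix_allowed = row$cc_suffix_allowed,
        applies_to = strsplit(row$applies_to, "|", fixed = TRUE)[[1]],
        genetic_only = row$genetic_only,
        biospecimen_only = row$biospecimen_only,
        version_introduced = row$version_introduced,
        description = row$description
      )
    })
    names(.cc_env$defs) <- reg$id
  }
  .cc_env$registry
}

#' Look up one code definition
#'
#' @param code_id a code identifier such as `"DS"` or `"NPU"` (case
#'   sensitive, upper case).
#' @return A list with the fields described in [cc_registry()], with
#'   `applies_to` split into a character vector.
#' @export
#' @examples
#' cc_definition("NRES")$description
#' cc_definition("CL")$biospecimen_only
cc_definition <- function(code_id) {
  cc_registry()
  def <- .cc_env$defs[[code_id]]
  if (is.null(def)) {
    cc_abort("cc_unknown_code_error",
             sprintf("unknown consent code: '%s'", code_id),
             token = code_id)
  }
  def
}

#' List code definitions, optionally filtered
#'
#' Order is stable: the canonical registry row order.
#'
#' @param tier optional tier filter (`"PRIMARY"`, `"SECONDARY"`,
#'   `"REQUIREMENT"`, `"PERMISSION"`).
#' @param parameterized optional logical filter.
#' @param applies_to optional `"data"` or `"biospecimen"`: keep codes
#'   applicable to that resource kind.
#' @param genetic_only,biospecimen_only optional logical filters.
#' @return data.frame, a subset of [cc_registry()] rows.
#' @export
#' @examples
#' cc_codes(tier = "PRIMARY")$id
#' cc_codes(biospecimen_only = TRUE)$id
cc_codes <- function(tier = NULL, parameterized = NULL, applies_to = NULL,
                     genetic_only = NULL, biospecimen_only = NULL) {
  reg <- cc_registry()
  keep <- rep(TRUE, nrow(reg))
  if (!is.null(tier)) {
    tier <- match.arg(tier, c("PRIMARY", "SECONDARY", "REQUIREMENT",
                              "PERMISSION"), several.ok = TRUE)
    keep <- keep & reg$tier %in% tier
  }
  if (!is.null(parameterized)) keep <- keep & reg$parameterized == parameterized
  if (!is.null(applies_to)) {
    applies_to <- match.arg(applies_to, c("data", "biospecimen"))
    keep <- keep & vapply(strsplit(reg$applies_to, "|", fixed = TRUE),
                          function(a) applies_to %in% a, logical(1))
  }
  if (!is.null(genetic_only)) keep <- keep & reg$genetic_only == genetic_only
  if (!is.null(biospecimen_only)) {
    keep <- keep & reg$biospecimen_only == biospecimen_only
  }
  reg[keep, , drop = FALSE]
}

# code groups used by the validator and the decision engine
cc_obligation_codes <- function() {
  c("PUB", "COL", "ROR", "RTN", "IRB", "BEN", "OS", "MOR")
}
cc_gate_codes <- function() c("NPU", "NCU", "GS", "TS", "US", "PS", "IS")
cc_permission_codes <- function() {
  c("CQ", "CS", "CR", "HR", "ARA", "GEN", "CL")
}
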