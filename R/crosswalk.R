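# Crosswalks to GA4GH DUO terms and HL7 research Purpose-of-Use codes.
#
# The DUO correspondence is versioned against the DUO 2021-02-23 snapshot.
# Mapped rows carry fidelity "exact"; codes with no DUO/HL7 counterpart are
# reported with fidelity "none"; three DUO accessions (DUO:0000042,
# DUO:0000015, DUO:0000046) are carried as target-only entries because they
# look similar to, but mean something different from, a Consent Code —
# each carries a caution note. The GRU(CC) -> HRESCH HL7 mapping is an
# interpretation (fidelity "broader"), not a stated equivalence.

cc_duo_version <- function() "2021-02-23"

load_crosswalk <- function(file, cache_slot) {
  if (!is.null(.cc_env[[cache_slot]])) return(.cc_env[[cache_slot]])
  path <- system.file("extdata", file, package = "consentcodes",
                      mustWork = TRUE)
  x <- utils::read.delim(path, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, colClasses = "character",
                         encoding = "UTF-8")
  if (!"caution" %in% names(x)) x$caution <- ""
  x$caution[is.na(x$caution)] <- ""
  .cc_env[[cache_slot]] <- x
  x
}

duo_table <- function() load_crosswalk("duo_crosswalk.tsv", "duo")
hl7_table <- function() load_crosswalk("hl7_pou_crosswalk.tsv", "hl7")

new_entry <- function(consent_code, target_system, target_id, fidelity,
                      caution = "", parameter = NULL, target_name = NULL) {
  structure(
    list(consent_code = if (is.null(consent_code) || !nzchar(consent_code))
                          NULL else consent_code,
         target_system = target_system,
         target_id = if (is.null(target_id) || !nzchar(target_id)) NULL
                     else target_id,
         fidelity = fidelity,
         caution = caution,
         parameter = parameter,
         target_name = target_name),
    class = "cc_crosswalk_entry"
  )
}

#' @export
print.cc_crosswalk_entry <- function(x, ...) {
  cat("<crosswalk> ",
      if (is.null(x$consent_code)) "(target only)" else x$consent_code,
      " -> ",
      if (is.null(x$target_id)) sprintf("not in %s", x$target_system)
      else x$target_id,
      " [", x$fidelity, "]\n", sep = "")
  if (nzchar(x$caution)) cat("  caution: ", x$caution, "\n", sep = "")
  invisible(x)
}

as_instance <- function(code) {
  if (inherits(code, "cc_instance")) return(code)
  tryCatch(
    cc_parse_token(code),
    # bare parameterized ids ("DS", "RS") are acceptable for mapping:
    # the crosswalk is defined on the code, not on its parameter
    cc_param_arity_error = function(e) {
      raw <- trimws(code)
      cc <- grepl("\\([Cc][Cc]\\)$", raw)
      id <- toupper(trimws(sub("\\([Cc][Cc]\\)$", "", raw)))
      def <- cc_definition(id)
      structure(list(id = def$id, tier = def$tier, parameter = NULL,
                     parameter_norm = NULL, cc = cc),
                class = "cc_instance")
    }
  )
}

#' Map a consent code to its DUO term
#'
#' @param code a `cc_instance` or a token string.
#' @return A `cc_crosswalk_entry`. Unmapped codes ("not in DUO") return
#'   `target_id = NULL`, `fidelity = "none"`, with any caution from the
#'   correspondence table; instance parameters are carried through in the
#'   `parameter` field.
#' @export
#' @examples
#' cc_to_duo("NRES")$target_id
#' cc_to_duo("HPOA")$fidelity
cc_to_duo <- function(code) {
  inst <- as_instance(code)
  tab <- duo_table()
  row <- tab[tab$consent_code == inst$id, , drop = FALSE]
  if (nrow(row) != 1L) {
    cc_abort("cc_unknown_code_error",
             sprintf("no DUO correspondence row for code '%s'", inst$id),
             token = inst$id)
  }
  new_entry(inst$id, "DUO", row$target_id, row$fidelity, row$caution,
            parameter = inst$parameter)
}

#' Map a DUO accession back to its consent code
#'
#' Inverse of [cc_to_duo()] on the mapped subset. Known target-only
#' accessions (e.g. `DUO:0000042`, the general-research-use term broader
#' than GRU(CC)) return `consent_code = NULL` with a caution; unknown
#' accessions return a bare target-only entry.
#'
#' @param duo_id accession of the form `DUO:0000005`.
#' @return A `cc_crosswalk_entry`.
#' @export
#' @examples
#' cc_from_duo("DUO:0000007")$consent_code
cc_from_duo <- function(duo_id) {
  if (length(duo_id) != 1L || !grepl("^DUO:[0-9]{7}$", duo_id)) {
    cc_abort("cc_syntax_error",
             sprintf("malformed DUO accession: '%s'", duo_id))
  }
  tab <- duo_table()
  row <- tab[tab$target_id == duo_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(new_entry(NULL, "DUO", duo_id, "none",
                     "accession not in the packaged correspondence table"))
  }
  row <- row[1L, , drop = FALSE]
  new_entry(row$consent_code, "DUO", row$target_id,
            if (nzchar(row$consent_code)) row$fidelity else "none",
            row$caution)
}

#' Map a consent code to HL7 research Purpose-of-Use codes
#'
#' Stated equivalences (BIOHRCH = HMB(CC), DSHRCH = DS-\[XX\](CC),
#' POAHRCH = HPOA) are returned with fidelity `"exact"`; RS/TDS/GSO map to
#' DISHRCH with fidelity `"related"` (DISHRCH "can be equivalent" to any of
#' the three); GRU(CC) maps to HRESCH with fidelity `"broader"` as a
#' package interpretation. All other codes are unmapped.
#'
#' @param code a `cc_instance` or token string.
#' @return list of `cc_crosswalk_entry` (length 1; at most one
#'   exact-fidelity entry per code).
#' @export
#' @examples
#' cc_to_hl7("HMB(CC)")[[1]]$target_id
cc_to_hl7 <- function(code) {
  inst <- as_instance(code)
  cc_definition(inst$id)  # unknown-code check
  tab <- hl7_table()
  rows <- tab[tab$consent_code == inst$id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(list(new_entry(inst$id, "HL7_POU", NULL, "none",
                          parameter = inst$parameter)))
  }
  lapply(seq_len(nrow(rows)), function(k) {
    new_entry(inst$id, "HL7_POU", rows$target_id[k], rows$fidelity[k],
              rows$caution[k], parameter = inst$parameter,
              target_name = rows$target_name[k])
  })
}

#' Coverage audit of both crosswalks
#'
#' One row per consent code with its DUO and HL7 status, followed by one
#' row per target-only identifier in either system, so the row count is
#' conserved: registry size + target-only entries.
#'
#' @return data.frame with columns `consent_code`, `duo_target`,
#'   `duo_fidelity`, `hl7_target`, `hl7_fidelity`, `caution`.
#' @export
#' @examples
#' rep <- cc_coverage_report()
#' sum(rep$duo_fidelity == "none" & rep$consent_code != "")
cc_coverage_report <- function() {
  reg <- cc_registry()
  duo <- duo_table()
  hl7 <- hl7_table()
  rows <- lapply(reg$id, function(id) {
    d <- duo[duo$consent_code == id, , drop = FALSE]
    h <- hl7[hl7$consent_code == id, , drop = FALSE]
    data.frame(
      consent_code = id,
      duo_target = if (nrow(d) && nzchar(d$target_id[1])) d$target_id[1]
                   else "",
      duo_fidelity = if (nrow(d)) d$fidelity[1] else "none",
      hl7_target = if (nrow(h)) paste(h$target_id, collapse = ";") else "",
      hl7_fidelity = if (nrow(h)) paste(h$fidelity, collapse = ";")
                     else "none",
      caution = paste(c(if (nrow(d) && nzchar(d$caution[1])) d$caution[1],
                        if (nrow(h)) h$caution[nzchar(h$caution)]),
                      collapse = " | "),
      stringsAsFactors = FALSE
    )
  })
  duo_only <- duo[!nzchar(duo$consent_code), , drop = FALSE]
  hl7_only <- hl7[!nzchar(hl7$consent_code), , drop = FALSE]
  rows <- c(rows,
    lapply(seq_len(nrow(duo_only)), function(k) {
      data.frame(consent_code = "", duo_target = duo_only$target_id[k],
                 duo_fidelity = "none", hl7_target = "",
                 hl7_fidelity = "", caution = duo_only$caution[k],
                 stringsAsFactors = FALSE)
    }),
    lapply(seq_len(nrow(hl7_only)), function(k) {
      data.frame(consent_code = "", duo_target = "", duo_fidelity = "",
                 hl7_target = hl7_only$target_id[k], hl7_fidelity = "none",
                 caution = hl7_only$caution[k], stringsAsFactors = FALSE)
    }))
  out <- do.call(rbind, rows)
  attr(out, "duo_version") <- cc_duo_version()
  out
}
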