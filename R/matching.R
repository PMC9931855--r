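# Term and region matching used by the decision engine.
#
# Code parameters ("[XX]") are free text: the default matcher is normalized
# exact equality. An optional child -> parent term hierarchy enables
# subsumption matching, so a request studying "breast cancer" satisfies
# DS-CANCER. Ontology binding (e.g. to MONDO/DOID) is a deployment concern:
# load any ontology's is-a edges as the hierarchy table.

#' Read a term hierarchy table
#'
#' @param path TSV with header columns `term` and `parent` (one edge per
#'   row, child to parent).
#' @return data.frame with normalized `term` and `parent` columns.
#' @export
#' @examples
#' h <- cc_read_hierarchy(system.file("extdata",
#'   "example_disease_hierarchy.tsv", package = "consentcodes"))
cc_read_hierarchy <- function(path) {
  h <- utils::read.delim(path, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("term", "parent") %in% names(h))) {
    cc_abort("cc_schema_error",
             "hierarchy table needs 'term' and 'parent' columns")
  }
  h$term <- cc_normalize_term(h$term)
  h$parent <- cc_normalize_term(h$parent)
  h
}

#' Build a term matcher
#'
#' Returns a function `f(request_terms, parameter)` that is `TRUE` when any
#' request term equals the code parameter, or (with a hierarchy) is a
#' descendant of it. All comparison is on [cc_normalize_term()] normal
#' forms.
#'
#' @param hierarchy optional data.frame as returned by
#'   [cc_read_hierarchy()] (or `NULL` for exact matching only).
#' @return a matcher function.
#' @export
#' @examples
#' m <- cc_term_matcher()
#' m("Cancer", "CANCER")
cc_term_matcher <- function(hierarchy = NULL) {
  parents <- NULL
  if (!is.null(hierarchy)) {
    parents <- split(hierarchy$parent, hierarchy$term)
  }
  ancestors <- function(term) {
    out <- character(0)
    frontier <- term
    while (length(frontier)) {
      up <- unique(unlist(parents[frontier], use.names = FALSE))
      up <- setdiff(up, out)  # guards against cycles
      out <- c(out, up)
      frontier <- up
    }
    out
  }
  function(request_terms, parameter) {
    if (length(request_terms) == 0L) return(FALSE)
    terms <- cc_normalize_term(request_terms)
    param <- cc_normalize_term(parameter)
    if (param %in% terms) return(TRUE)
    if (!is.null(parents)) {
      for (t in terms) if (param %in% ancestors(t)) return(TRUE)
    }
    FALSE
  }
}

#' Load a geographic region membership table
#'
#' The packaged default groups ISO-3166 alpha-2 country codes into common
#' regions (EU, EEA, UK, NORTH_AMERICA, AFRICA). It is a convenience
#' default, not part of the vocabulary: override it with any
#' `region`/`member` table matching your data access agreements.
#'
#' @param path optional TSV with header columns `region` and `member`;
#'   `NULL` loads the packaged default.
#' @return data.frame with normalized `region` and `member` columns.
#' @export
cc_region_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cc_env$regions)) return(.cc_env$regions)
    path <- system.file("extdata", "regions.tsv", package = "consentcodes",
                        mustWork = TRUE)
    default <- TRUE
  } else default <- FALSE
  r <- utils::read.delim(path, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("region", "member") %in% names(r))) {
    cc_abort("cc_schema_error",
             "region table needs 'region' and 'member' columns")
  }
  r$region <- cc_normalize_term(r$region)
  r$member <- cc_normalize_term(r$member)
  if (default) .cc_env$regions <- r
  r
}

# TRUE when `geography` lies within `region` under the table (a region is
# also a member of itself); fail-closed on unknown regions/geographies
cc_in_region <- function(geography, region, region_table) {
  if (is.null(geography) || !nzchar(geography)) return(FALSE)
  geo <- cc_normalize_term(geography)
  reg <- cc_normalize_term(region)
  if (geo == reg) return(TRUE)
  if (is.null(region_table)) return(FALSE)
  geo %in% region_table$member[region_table$region == reg]
}
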