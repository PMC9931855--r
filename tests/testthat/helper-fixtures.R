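# Independently hand-transcribed vocabulary fixtures used to audit the
# packaged tables. Typed from the printed v4 code table and the two
# correspondence tables directly, NOT derived from the package's TSVs.

# (id, tier, parameterized, applies_to) for every v4 code, in table order
vocabulary_fixture <- function() {
  tuples <- c(
    "NRES PRIMARY FALSE data+biospecimen",
    "GRU PRIMARY FALSE data+biospecimen",
    "HMB PRIMARY FALSE data+biospecimen",
    "DS PRIMARY TRUE data+biospecimen",
    "POA PRIMARY FALSE data+biospecimen",
    "TDS SECONDARY TRUE data+biospecimen",
    "RS SECONDARY TRUE data+biospecimen",
    "NDS SECONDARY TRUE data+biospecimen",
    "HPOA SECONDARY FALSE data+biospecimen",
    "NMDS SECONDARY FALSE data",
    "RUO SECONDARY FALSE data",
    "GSO SECONDARY FALSE data+biospecimen",
    "NPU REQUIREMENT FALSE data+biospecimen",
    "NCU REQUIREMENT FALSE data+biospecimen",
    "BEN REQUIREMENT FALSE data+biospecimen",
    "PUB REQUIREMENT FALSE data+biospecimen",
    "COL REQUIREMENT TRUE data+biospecimen",
    "ROR REQUIREMENT TRUE data+biospecimen",
    "RTN REQUIREMENT FALSE data+biospecimen",
    "IRB REQUIREMENT FALSE data+biospecimen",
    "GS REQUIREMENT TRUE data+biospecimen",
    "MOR REQUIREMENT TRUE data+biospecimen",
    "TS REQUIREMENT TRUE data+biospecimen",
    "OS REQUIREMENT FALSE data+biospecimen",
    "US REQUIREMENT FALSE data+biospecimen",
    "PS REQUIREMENT FALSE data+biospecimen",
    "IS REQUIREMENT FALSE data+biospecimen",
    "CQ PERMISSION FALSE data+biospecimen",
    "CS PERMISSION FALSE data+biospecimen",
    "CR PERMISSION FALSE data+biospecimen",
    "HR PERMISSION FALSE data+biospecimen",
    "ARA PERMISSION TRUE data+biospecimen",
    "GEN PERMISSION FALSE biospecimen",
    "CL PERMISSION FALSE biospecimen"
  )
  parts <- strsplit(tuples, " ", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, "", 1),
    tier = vapply(parts, `[`, "", 2),
    parameterized = vapply(parts, `[`, "", 3) == "TRUE",
    applies_to = gsub("+", "|", vapply(parts, `[`, "", 4), fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

# codes added after v1 (bold in the printed table), per the narrative
post_v1_codes <- function() {
  c("NDS", "OS", "BEN", "NCU", "HPOA", "TDS", "ROR", "RTN",
    "CQ", "CS", "CR", "HR", "ARA", "GEN", "CL")
}

# the full DUO correspondence, "" meaning "not in DUO"
duo_fixture <- function() {
  c(NRES = "DUO:0000004", GRU = "DUO:0000005", HMB = "DUO:0000006",
    DS = "DUO:0000007", POA = "DUO:0000011",
    TDS = "", RS = "DUO:0000012", NDS = "", HPOA = "",
    NMDS = "", RUO = "DUO:0000014", GSO = "DUO:0000016",
    NPU = "DUO:0000045", NCU = "", BEN = "", PUB = "DUO:0000019",
    COL = "DUO:0000020", ROR = "", RTN = "DUO:0000029",
    IRB = "DUO:0000021", GS = "DUO:0000022", MOR = "DUO:0000024",
    TS = "DUO:0000025", OS = "", US = "DUO:0000026", PS = "DUO:0000027",
    IS = "DUO:0000028", CQ = "", CS = "", CR = "", HR = "", ARA = "",
    GEN = "", CL = "")
}

# a dummy parameter a parameterized code can carry in round-trip loops
dummy_param <- function(id) {
  role <- cc_definition(id)$parameter_role
  if (role == "months") "24" else if (role == "date") "2031-12-31" else "XX"
}

# path to the installed CLI script and an Rscript invocation helper
cli_path <- function() {
  system.file("cli", "consentcodes.R", package = "consentcodes",
              mustWork = TRUE)
}
run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(cli_path(), args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))
  ))
  list(stdout = out, status = attr(out, "status") %||% 0L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
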