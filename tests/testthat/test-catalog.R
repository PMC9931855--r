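demo_catalog <- function() {
  list(
    cc_catalog_entry("cohortA", "imaging cohort", c("GRU(CC)", "PUB"),
                     resource_kind = "data"),
    cc_catalog_entry("cohortB", "biomedical cohort", "HMB(CC)",
                     resource_kind = "data"),
    cc_catalog_entry("cohortC", "ancestry panel", "POA",
                     resource_kind = "data")
  )
}

test_that("catalogs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  cc_write_catalog(demo_catalog(), path)
  back <- cc_read_catalog(path)
  expect_length(back, 3L)
  expect_identical(vapply(back, function(e) e$dataset_id, character(1)),
                   c("cohortA", "cohortB", "cohortC"))
  expect_identical(back[[1]]$profile_tokens, c("GRU(CC)", "PUB"))
  expect_identical(back[[2]]$resource_kind, "data")
})

test_that("TSV catalogs are read with comma-separated token lists", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "dataset_id\ttitle\tresource_kind\tis_genetic_resource\tprofile_tokens",
    "d1\tone\tdata\tTRUE\tHMB(CC),GSO,PUB",
    "d2\ttwo\tdata,biospecimen\tFALSE\tNRES"
  ), path)
  cat <- cc_read_catalog(path)
  expect_length(cat, 2L)
  expect_identical(cat[[1]]$profile_tokens, c("HMB(CC)", "GSO", "PUB"))
  expect_true(cat[[1]]$is_genetic_resource)
})

test_that("invalid entries abort in strict mode and are skipped leniently", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(dataset_id = "ok", profile_tokens = list("HMB(CC)"),
         resource_kind = list("data")),
    list(dataset_id = "bad", profile_tokens = list("GRU(CC)", "HPOA"),
         resource_kind = list("data"))
  ), path, auto_unbox = TRUE)

  err <- expect_error(cc_read_catalog(path), class = "cc_schema_error")
  expect_match(conditionMessage(err), "bad")   # names the offending entry
  expect_match(conditionMessage(err), "HPOA")  # and the offending rule

  expect_warning(lenient <- cc_read_catalog(path, strictness = "lenient"),
                 "bad")
  expect_length(lenient, 1L)
  expect_identical(lenient[[1]]$dataset_id, "ok")
})

test_that("filtering decides every entry and is order-invariant", {
  catalog <- demo_catalog()
  poa_req <- cc_request("poa", attestations = c(PUB = TRUE))
  res <- cc_filter_catalog(catalog, poa_req)
  statuses <- vapply(res$decisions, function(d) d$status, character(1))
  expect_identical(
    statuses,
    c(cohortA = "PERMIT_WITH_OBLIGATIONS", cohortB = "DENY",
      cohortC = "PERMIT"))
  expect_identical(unname(res$summary),
                   c(1L, 1L, 1L))

  shuffled <- cc_filter_catalog(catalog[c(3, 1, 2)], poa_req)
  expect_identical(names(shuffled$decisions), names(res$decisions))
  expect_identical(
    vapply(shuffled$decisions, function(d) d$status, character(1)),
    statuses)
})

test_that("decisions round-trip through JSON and TSV with stable columns", {
  res <- cc_filter_catalog(demo_catalog(),
                           cc_request("poa", attestations = c(PUB = TRUE)))
  for (fmt in c("json", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    cc_write_decisions(res, path, format = fmt)
    back <- cc_read_decisions(path)
    expect_identical(names(back),
                     c("dataset_id", "status", "obligations",
                       "denial_reasons"))
    expect_identical(back$dataset_id, names(res$decisions))
    expect_identical(back$status,
                     unname(vapply(res$decisions, function(d) d$status,
                                   character(1))))
    expect_identical(back$obligations[back$dataset_id == "cohortA"], "PUB")
  }

  # empty decision map: header-only TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  cc_write_decisions(structure(list(decisions = list(),
                                    summary = c(PERMIT = 0L,
                                                PERMIT_WITH_OBLIGATIONS = 0L,
                                                DENY = 0L)),
                               class = "cc_decision_set"),
                     path, format = "tsv")
  lines <- readLines(path)
  expect_identical(lines, "dataset_id\tstatus\tobligations\tdenial_reasons")
})

test_that("requests round-trip through their JSON representation", {
  r <- cc_random_request(99)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cc_request_to_list(r), path, auto_unbox = TRUE)
  back <- cc_request_from_json(path)
  p <- cc_random_profile(77)
  expect_identical(cc_decision_key(cc_evaluate(p, back)),
                   cc_decision_key(cc_evaluate(p, r)))
  expect_identical(back$purpose_domain, r$purpose_domain)
  expect_identical(back$requester$org_type, r$requester$org_type)
})
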