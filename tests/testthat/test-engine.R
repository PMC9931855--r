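health_req <- function(...) cc_request("health", ...)

test_that("primary categories bound the purpose region", {
  hmb <- cc_parse_token("HMB(CC)")
  gru <- cc_parse_token("GRU(CC)")
  poa <- cc_parse_token("POA")
  hpoa <- cc_parse_token("HPOA")

  # HMB excludes population origins/ancestry research...
  res <- cc_purpose_permitted(hmb, list(), cc_request("poa"))
  expect_false(res$permitted)
  expect_true("PURPOSE_DOMAIN" %in% res$reasons$rule)
  # ...unless HPOA carves health-related ancestry analysis back in
  expect_true(cc_purpose_permitted(
    hmb, list(hpoa), cc_request("poa", poa_health_related = TRUE))$permitted)
  expect_false(cc_purpose_permitted(
    hmb, list(hpoa), cc_request("poa", poa_health_related = FALSE))$permitted)

  # GRU admits all three domains, including plain ancestry research
  expect_true(cc_purpose_permitted(gru, list(), cc_request("poa"))$permitted)
  expect_true(cc_purpose_permitted(
    gru, list(), cc_request("other_biological"))$permitted)

  # POA admits ancestry only
  expect_true(cc_purpose_permitted(poa, list(), cc_request("poa"))$permitted)
  expect_false(cc_purpose_permitted(poa, list(), health_req())$permitted)

  # HMB excludes other biological research
  expect_false(cc_purpose_permitted(
    hmb, list(), cc_request("other_biological"))$permitted)
})

test_that("DS requires a disease match; NDS vetoes matching diseases", {
  ds <- cc_parse_token("DS-CANCER(CC)")
  expect_true(cc_purpose_permitted(
    ds, list(), health_req(disease_terms = "CANCER"))$permitted)
  res <- cc_purpose_permitted(ds, list(),
                              health_req(disease_terms = "HIV"))
  expect_false(res$permitted)
  expect_true("DS_MATCH" %in% res$reasons$rule)

  gru <- cc_parse_token("GRU(CC)")
  nds <- cc_parse_token("NDS-HIV")
  res <- cc_purpose_permitted(gru, list(nds),
                              health_req(disease_terms = "HIV"))
  expect_false(res$permitted)
  expect_true("NDS_EXCLUDED" %in% res$reasons$rule)
  expect_true(cc_purpose_permitted(
    gru, list(nds), health_req(disease_terms = "CANCER"))$permitted)

  # with a hierarchy, a child disease matches a DS ancestor
  m <- cc_term_matcher(cc_read_hierarchy(
    system.file("extdata", "example_disease_hierarchy.tsv",
                package = "consentcodes")))
  expect_true(cc_purpose_permitted(
    ds, list(), health_req(disease_terms = "breast cancer"),
    term_matcher = m)$permitted)
})

test_that("TDS, RS, GSO and NMDS narrow the region conjunctively", {
  hmb <- cc_parse_token("HMB(CC)")
  expect_false(cc_purpose_permitted(
    hmb, list(cc_parse_token("TDS-RITUXIMAB")),
    health_req(therapy_terms = "STATINS"))$permitted)
  expect_true(cc_purpose_permitted(
    hmb, list(cc_parse_token("TDS-RITUXIMAB")),
    health_req(therapy_terms = "rituximab"))$permitted)

  expect_false(cc_purpose_permitted(
    hmb, list(cc_parse_token("RS-PEDIATRIC")), health_req())$permitted)
  expect_true(cc_purpose_permitted(
    hmb, list(cc_parse_token("RS-PEDIATRIC")),
    health_req(research_type_terms = "pediatric"))$permitted)

  expect_false(cc_purpose_permitted(
    hmb, list(cc_parse_token("GSO")),
    health_req(uses_only_nongenetic_data = TRUE))$permitted)

  # NMDS permits methods development only within the other limitations
  expect_false(cc_purpose_permitted(
    hmb, list(cc_parse_token("NMDS")),
    health_req(methods_dev = "general"))$permitted)
  expect_true(cc_purpose_permitted(
    hmb, list(cc_parse_token("NMDS")),
    health_req(methods_dev = "within_bounds"))$permitted)
  # with NMDS absent, general methods research is admitted only under GRU
  expect_false(cc_purpose_permitted(
    hmb, list(), health_req(methods_dev = "general"))$permitted)
  expect_true(cc_purpose_permitted(
    cc_parse_token("GRU(CC)"), list(),
    health_req(methods_dev = "general"))$permitted)
})

test_that("fact gates check requester attributes", {
  rt <- cc_region_table()
  gate <- function(tokens, ...) {
    reqs <- lapply(tokens, cc_parse_token)
    cc_evaluate_gates(reqs, cc_request("health", ...), rt)
  }
  expect_identical(
    gate("NPU", requester = cc_requester("for_profit"))$rule, "NPU_ORG")
  expect_length(gate("NPU", requester = cc_requester("not_for_profit"))$rule,
                0L)
  # NPU and NCU constrain different axes: a not-for-profit commercial use
  f <- cc_evaluate_gates(
    lapply(c("NPU", "NCU"), cc_parse_token),
    cc_request("health",
               requester = cc_requester("not_for_profit",
                                        commercial_purpose = TRUE)), rt)
  expect_identical(f$rule, "NCU_COMMERCIAL")

  expect_length(gate("TS-12", duration_months = 6)$rule, 0L)
  expect_identical(gate("TS-12", duration_months = 24)$rule, "TS_DURATION")
  expect_identical(gate("TS-12")$rule, "TS_DURATION")  # open-ended: closed

  expect_length(
    gate("GS-EU", requester = cc_requester(geography = "FR"))$rule, 0L)
  expect_identical(
    gate("GS-EU", requester = cc_requester(geography = "JP"))$rule,
    "GS_REGION")
})

test_that("US/PS/IS gates need an approved-entity list and a member id", {
  rt <- cc_region_table()
  us <- list(cc_parse_token("US"))
  req <- cc_request("health", requester = cc_requester(user_id = "U1"))
  # no list attached to the resource: requires named approval, fails closed
  f <- cc_evaluate_gates(us, req, rt, approved_entities = NULL)
  expect_identical(f$rule, "US_APPROVAL")
  expect_match(f$message, "requires named approval")
  # list present, requester approved
  expect_length(cc_evaluate_gates(us, req, rt,
    approved_entities = list(users = c("U1", "U2")))$rule, 0L)
  # list present, requester not on it
  expect_identical(cc_evaluate_gates(us, req, rt,
    approved_entities = list(users = "U9"))$rule, "US_APPROVAL")
})

test_that("a non-integer TS parameter is a gate error", {
  p <- cc_parse_profile("HMB(CC)")
  inst <- cc_instance("TS", "12")
  inst$parameter <- "soon"  # bypass construction-time validation
  expect_error(
    cc_evaluate_gates(list(inst), cc_request("health"), cc_region_table()),
    class = "cc_gate_error")
})

test_that("NRES permits any request with no obligations", {
  nres <- cc_parse_profile("NRES")
  for (r in list(cc_request("poa", clinical_reference_use = TRUE),
                 cc_request("health", methods_dev = "general",
                            requester = cc_requester("for_profit", TRUE)),
                 cc_request("other_biological",
                            biospecimen_intents = "derive_cell_lines"))) {
    d <- cc_evaluate(nres, r)
    expect_identical(d$status, "PERMIT")
    expect_length(d$obligations, 0L)
  }
})

test_that("attested obligations yield PERMIT_WITH_OBLIGATIONS", {
  p <- cc_parse_profile(c("HMB(CC)", "PUB", "IRB"))
  d <- cc_evaluate(p, cc_request("health",
                                 attestations = c(PUB = TRUE, IRB = TRUE)))
  expect_identical(d$status, "PERMIT_WITH_OBLIGATIONS")
  expect_setequal(d$obligations, c("PUB", "IRB"))

  # missing attestations fail closed, naming what would flip the outcome
  d <- cc_evaluate(p, cc_request("health", attestations = c(PUB = TRUE)))
  expect_identical(d$status, "DENY")
  expect_identical(d$denial_reasons$rule, "OBLIGATION_UNATTESTED")
  expect_identical(d$denial_reasons$code, "IRB")
  expect_match(d$denial_reasons$message, "attesting IRB")
})

test_that("gates deny: for-profit requester against an NPU profile", {
  p <- cc_parse_profile(c("DS-CANCER(CC)", "NPU"))
  d <- cc_evaluate(p, cc_request("health", disease_terms = "CANCER",
                                 requester = cc_requester("for_profit")))
  expect_identical(d$status, "DENY")
  expect_identical(d$denial_reasons$rule, "NPU_ORG")
})

test_that("clinical reference use needs an effective (CC) flag", {
  # RUO prevails over (CC)
  p <- cc_parse_profile(c("HMB(CC)", "RUO"), validate = FALSE)
  d <- cc_evaluate(p, cc_request("health", clinical_reference_use = TRUE))
  expect_identical(d$status, "DENY")
  expect_true("CLINICAL_REFERENCE" %in% d$denial_reasons$rule)
  expect_identical(d$denial_reasons$code, "RUO")

  # a plain primary without (CC) also denies
  d <- cc_evaluate(cc_parse_profile("HMB"),
                   cc_request("health", clinical_reference_use = TRUE))
  expect_identical(d$denial_reasons$rule, "CLINICAL_REFERENCE")

  # (CC) without RUO permits
  d <- cc_evaluate(cc_parse_profile("HMB(CC)"),
                   cc_request("health", clinical_reference_use = TRUE))
  expect_identical(d$status, "PERMIT")
})

test_that("biospecimen intents require their permission codes", {
  p <- cc_parse_profile(c("DS-ALS(CC)", "GEN"),
                        resource_kind = "biospecimen")
  d <- cc_evaluate(p, cc_request("health", disease_terms = "ALS",
                                 biospecimen_intents = "derive_cell_lines"))
  expect_identical(d$status, "DENY")
  expect_identical(d$denial_reasons$rule, "INTENT_CL")

  d <- cc_evaluate(p, cc_request("health", disease_terms = "ALS",
                                 biospecimen_intents =
                                   "extract_nucleic_acids"))
  expect_identical(d$status, "PERMIT")
  expect_identical(d$granted_permissions, "GEN")

  full <- cc_parse_profile(c("DS-ALS(CC)", "GEN", "CL", "CQ"),
                           resource_kind = "biospecimen")
  d <- cc_evaluate(full, cc_request("health", disease_terms = "ALS",
                                    biospecimen_intents =
                                      c("derive_cell_lines",
                                        "extract_nucleic_acids")))
  expect_identical(d$status, "PERMIT")
  expect_setequal(d$granted_permissions, c("GEN", "CL", "CQ"))
})

test_that("a MOR embargo cross-checks the planned publication date", {
  p <- cc_parse_profile(c("HMB(CC)", "MOR-2030-01-01"))
  early <- cc_request("health", attestations = c(MOR = TRUE),
                      requester = cc_requester(
                        planned_publication_date = "2028-06-01"))
  d <- cc_evaluate(p, early)
  expect_identical(d$status, "DENY")
  expect_identical(d$denial_reasons$rule, "MOR_DATE")

  late <- cc_request("health", attestations = c(MOR = TRUE),
                     requester = cc_requester(
                       planned_publication_date = "2030-06-01"))
  expect_identical(cc_evaluate(p, late)$status, "PERMIT_WITH_OBLIGATIONS")
})

test_that("decisions are deterministic and uphold their invariants", {
  p <- cc_parse_profile(c("DS-CANCER(CC)", "RS-PEDIATRIC", "NPU", "PUB"))
  r <- cc_request("health", disease_terms = "CANCER",
                  research_type_terms = "PEDIATRIC",
                  attestations = c(PUB = TRUE))
  expect_identical(cc_evaluate(p, r), cc_evaluate(p, r))
  d <- cc_evaluate(p, r)
  if (d$status == "PERMIT") expect_length(d$obligations, 0L)
  if (d$status == "DENY") expect_gt(length(d$denial_reasons$rule), 0L)
})

test_that("explanations render every firing and every denial reason", {
  nres <- cc_evaluate(cc_parse_profile("NRES"), cc_request("health"))
  expect_length(nres$trace$rule, 1L)

  p <- cc_parse_profile(c("DS-CANCER(CC)", "NPU", "IRB"))
  d <- cc_evaluate(p, cc_request("health", disease_terms = "HIV",
                                 requester = cc_requester("for_profit")))
  lines <- cc_explain(d)
  for (k in seq_along(d$denial_reasons$rule)) {
    expect_true(any(grepl(d$denial_reasons$rule[k], lines, fixed = TRUE)))
    expect_true(any(grepl(d$denial_reasons$message[k], lines, fixed = TRUE)))
  }
  # one rendered line per trace firing, plus denial restatements + status
  expect_length(lines, length(d$trace$rule) +
                         length(d$denial_reasons$rule) + 1L)
})
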