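test_that("token parsing handles parameters, (CC) flags and case", {
  ds <- cc_parse_token("DS-CANCER(CC)")
  expect_identical(ds$id, "DS")
  expect_identical(ds$parameter, "CANCER")
  expect_true(ds$cc)

  ts <- cc_parse_token("TS-24")
  expect_identical(ts$id, "TS")
  expect_identical(ts$parameter, "24")
  expect_false(ts$cc)

  # base codes are case-insensitive and whitespace is trimmed
  expect_identical(cc_render_token(cc_parse_token("  hmb(cc) ")), "HMB(CC)")
  # parameters may themselves contain hyphens
  expect_identical(cc_parse_token("DS-BREAST-CANCER")$parameter,
                   "BREAST-CANCER")
})

test_that("malformed tokens raise typed errors", {
  expect_error(cc_parse_token("PUB-XX"), class = "cc_param_arity_error")
  expect_error(cc_parse_token("DS"), class = "cc_param_arity_error")
  expect_error(cc_parse_token("NPU(CC)"), class = "cc_cc_not_allowed_error")
  expect_error(cc_parse_token("XYZ"), class = "cc_unknown_code_error")
  expect_error(cc_parse_token(""), class = "cc_syntax_error")
  expect_error(cc_parse_token("DS-"), class = "cc_syntax_error")
  expect_error(cc_parse_token("HMB(XX)"), class = "cc_syntax_error")
})

test_that("permissive mode carries unknown codes opaquely", {
  inst <- cc_parse_token("FOO-BAR", permissive = TRUE)
  expect_identical(inst$tier, "UNKNOWN")
  expect_identical(cc_render_token(inst), "FOO-BAR")
  profile <- cc_parse_profile(c("GRU(CC)", "FOO"), permissive = TRUE)
  report <- cc_validate_profile(profile)
  expect_true(report$valid)
  expect_true("UNKNOWN_CODE" %in% report$violations$rule)
})

test_that("render/parse round trip is the identity on canonical spellings", {
  reg <- cc_registry()
  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    params <- if (reg$parameterized[i]) dummy_param(id) else list(NULL)
    ccs <- if (reg$cc_suffix_allowed[i]) c(FALSE, TRUE) else FALSE
    for (param in params) {
      for (cc in ccs) {
        token <- cc_render_token(cc_instance(id, param, cc))
        expect_identical(cc_render_token(cc_parse_token(token)), token)
      }
    }
  }
})

test_that("a profile has exactly one primary and NRES stands alone", {
  expect_s3_class(
    cc_parse_profile(c("HMB(CC)", "HPOA", "PUB"),
                     is_genetic_resource = TRUE),
    "cc_profile")

  err <- expect_error(cc_parse_profile(c("GRU(CC)", "HMB(CC)")),
                      class = "cc_profile_error")
  expect_true("MULTIPLE_PRIMARY" %in% err$report$violations$rule)

  err <- expect_error(cc_parse_profile(c("PUB", "IRB")),
                      class = "cc_profile_error")
  expect_true("NO_PRIMARY" %in% err$report$violations$rule)

  err <- expect_error(cc_parse_profile(c("NRES", "PUB")),
                      class = "cc_profile_error")
  expect_true("NRES_COMPANIONS" %in% err$report$violations$rule)
})

test_that("scope rules: HPOA, GSO, biospecimen-only and data-only codes", {
  report <- cc_validate_profile(
    cc_parse_profile(c("GRU(CC)", "HPOA"), validate = FALSE))
  expect_false(report$valid)
  expect_true("HPOA_SCOPE" %in% report$violations$rule)

  report <- cc_validate_profile(
    cc_parse_profile(c("HMB(CC)", "GSO"), is_genetic_resource = FALSE,
                     validate = FALSE))
  expect_true("GSO_SCOPE" %in% report$violations$rule)

  report <- cc_validate_profile(
    cc_parse_profile(c("HMB(CC)", "GEN"), resource_kind = "data",
                     validate = FALSE))
  expect_true("BIOSPECIMEN_SCOPE" %in% report$violations$rule)

  report <- cc_validate_profile(
    cc_parse_profile(c("HMB(CC)", "RUO"), resource_kind = "biospecimen",
                     validate = FALSE))
  expect_true("APPLIES_SCOPE" %in% report$violations$rule)
})

test_that("a DS profile excluding its own disease is self-contradictory", {
  report <- cc_validate_profile(
    cc_parse_profile(c("DS-HIV(CC)", "NDS-HIV"), validate = FALSE))
  expect_false(report$valid)
  expect_true("SELF_CONTRADICTION" %in% report$violations$rule)
  # parameter comparison is case/whitespace insensitive
  report <- cc_validate_profile(
    cc_parse_profile(c("DS-HIV(CC)", "NDS-hiv "), validate = FALSE))
  expect_true("SELF_CONTRADICTION" %in% report$violations$rule)
  # a different excluded disease is fine
  expect_true(cc_validate_profile(
    cc_parse_profile(c("DS-HIV(CC)", "NDS-CANCER"),
                     validate = FALSE))$valid)
})

test_that("RUO on a (CC) primary warns that RUO prevails, but validates", {
  report <- cc_validate_profile(cc_parse_profile(c("HMB(CC)", "RUO"),
                                                 validate = FALSE))
  expect_true(report$valid)
  viol <- report$violations
  expect_true("CC_RUO_REDUNDANT" %in% viol$rule)
  expect_identical(viol$severity[viol$rule == "CC_RUO_REDUNDANT"], "warning")
})

test_that("validation is pure: identical profiles give identical reports", {
  p1 <- cc_parse_profile(c("DS-CANCER(CC)", "NPU", "PUB"), validate = FALSE)
  p2 <- cc_parse_profile(c("DS-CANCER(CC)", "NPU", "PUB"), validate = FALSE)
  expect_identical(cc_validate_profile(p1), cc_validate_profile(p2))
  expect_identical(cc_validate_profile(p1), cc_validate_profile(p1))
})

test_that("accepted profiles re-validate cleanly", {
  for (tokens in list(c("HMB(CC)", "HPOA", "PUB"),
                      c("DS-CANCER(CC)", "TDS-RITUXIMAB", "NPU", "IRB"),
                      c("POA", "GS-EU", "TS-12"),
                      "NRES")) {
    profile <- cc_parse_profile(tokens, is_genetic_resource = TRUE)
    expect_true(cc_validate_profile(profile)$valid)
    expect_identical(cc_profile_tokens(profile), tokens)
  }
})
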