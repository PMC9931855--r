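---
title: "Consent-code governance: semantics, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consent-code governance: semantics, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consentcodes)
```

## The problem

When research participants consent to data or biospecimen sharing, they
rarely consent to *anything*: common conditions restrict secondary use to
health research, to a disease area, to non-profit organisations, within a
geography or a time window, or attach obligations such as publication,
ethics review or return of results. Consent Codes are a controlled
vocabulary for those conditions. Attaching them to a dataset lets a Data
Access Committee — or an automated access system — decide whether a
concrete research plan is permissible without re-interpreting the original
consent materials.

This package implements the v4 vocabulary as executable rules. This
vignette records the semantics we implemented, the parameters that matter,
the choices we made where the vocabulary's prose leaves room, and what our
testing strategy does and does not establish.

## The decision model

A **profile** is the set of code instances attached to one resource. It
contains exactly one *primary* category, any number of *secondary*
modifiers, and any number of *requirement/permission* codes. A **request**
is a structured description of the proposed use: purpose domain (health /
other biological / population origins or ancestry), the disease, therapy
and research-type terms the study targets, flags for methods development,
clinical-reference use and non-genetic-only analysis, requester attributes
(organisation type, commercial purpose, geography, identifiers, planned
publication date), attestations, biospecimen intents and duration.

Evaluation is a conjunction of five independent stages, all failing
closed:

1. **Purpose region.** The primary fixes the admissible purpose region:
   `NRES` admits everything; `GRU(CC)` admits health, other biological
   research, and ancestry research; `HMB(CC)` admits health only;
   `DS-[X](CC)` admits health related to the named disease; `POA` admits
   ancestry research only. Secondary codes modify the region
   conjunctively: `TDS-[X]` and `RS-[X]` require a therapy / research-type
   match, `NDS-[X]` vetoes a disease, `GSO` vetoes purely non-genetic
   analysis, `NMDS` vetoes general methods development, and `HPOA` carves
   health-related ancestry analysis back into HMB/DS profiles.
2. **Fact gates.** `NPU` (organisation type), `NCU` (commercial purpose —
   deliberately broader than NPU: a not-for-profit commercial use fails
   NCU but passes NPU), `GS-[region]` (geography via a membership table),
   `TS-[months]` (requested duration), `US`/`PS`/`IS` (requester
   identifier must appear on an approved-entity list attached to the
   resource; an absent list fails with "requires named approval").
3. **Attestation obligations.** `PUB`, `COL`, `ROR`, `RTN`, `IRB`, `BEN`,
   `OS` and `MOR` cannot be fact-checked by software; the requester must
   attest to each. A missing attestation denies, and the denial reason
   names exactly which attestation would flip the outcome. `MOR-[date]` is
   additionally cross-checked against a stated planned publication date
   when one is given.
4. **Biospecimen permissions.** Deriving cell lines requires `CL`;
   extracting nucleic acids requires `GEN`. Other permission codes (`CQ`,
   `CS`, `CR`, `HR`, `ARA`) do not gate anything; they are reported as
   granted permissions.
5. **Clinical-reference use.** Permitted only under `NRES`, or when the
   primary carries `(CC)` and `RUO` is absent. The `(CC)` flag means the
   research data may serve as background *reference data* in clinical
   activities; it never covers using an individual's research data in
   their own care.

The result is `PERMIT`, `PERMIT_WITH_OBLIGATIONS` (all checks pass but
obligations attach) or `DENY`, with machine-stable denial rule ids and an
ordered trace that `cc_explain()` renders with the registry descriptions.

```{r example}
p <- cc_parse_profile(c("HMB(CC)", "HPOA", "PUB"), is_genetic_resource = TRUE)
r <- cc_request("poa", poa_health_related = TRUE,
                attestations = c(PUB = TRUE))
cc_evaluate(p, r)$status
```

## Profile validity

`cc_validate_profile()` is pure and reports rather than throws. Error
rules: a profile has exactly one primary; `NRES` admits no companions (see
below); `HPOA` attaches only to HMB/DS; `GSO` only to genetic resources;
`GEN`/`CL` only to biospecimen resources; `NMDS`/`RUO` (whose descriptions
speak of data only) only where the resource includes data; `DS-[X]`
combined with `NDS-[X]` is rejected as self-contradictory because the
permitted set is analytically empty; a non-integer `TS` parameter is an
error because the gate could never be evaluated. Warning rules: `RUO` on a
`(CC)` primary (redundant; RUO prevails), a non-ISO `MOR` date (the
embargo can then only be attested, not date-checked), and unknown codes in
permissive mode (carried opaquely and ignored by the engine, for forward
compatibility).

## Parameters that matter

* **Term matching** (`cc_term_matcher()`): code parameters are free text,
  so the default is exact equality after trimming, whitespace collapsing
  and upper-casing. Supplying a child→parent hierarchy table enables
  subsumption, so "breast cancer" satisfies `DS-CANCER`. Matching is
  always upward (a child satisfies an ancestor parameter, never the
  reverse). Binding to a real ontology is a deployment concern: load its
  is-a edges as the hierarchy.
* **Region table** (`cc_region_table()`): `GS-[region]` needs a
  region→member table. The packaged default groups ISO-3166 alpha-2
  country codes into EU, EEA, UK, NORTH_AMERICA and AFRICA as a
  convenience; it is package-authored reference data, not vocabulary
  content, and should be overridden to match the governing access
  agreement. Unknown regions or geographies fail closed.
* **`hpoa_disease_scoped`** (default `TRUE`): on a `DS` profile with
  `HPOA`, must health-related ancestry analysis also match the DS disease?
  The vocabulary does not say; we default to the most restrictive reading
  and expose the switch.
* **`TS` / `MOR` units**: integer months and ISO-8601 dates respectively.
  A request with no stated duration fails a `TS` gate (fail closed).

## Open interpretation choices

Three places where the printed vocabulary underdetermines behaviour; in
each case we chose once, documented here, and made the choice inspectable:

* **Methods development with `NMDS` absent.** The code's name ("no
  'general methods' research") and its description ("includes methods
  development research ... ONLY within the bounds") pull in different
  directions for profiles that *don't* carry it. We treat
  `within_bounds` methods work as acceptable whenever the host purpose
  is, and `general` methods research as lying outside the HMB/DS/POA
  purpose regions — admissible only under `GRU` or `NRES`. This mirrors
  the map picture in which general methods development sits outside the
  health-purpose nesting.
* **Companions on `NRES`.** `NRES` is described as no restrictions at
  all (the open-access category), which we read as forbidding companion
  codes; the rule is downgradable via `allow_nres_companions` for
  catalogs that disagree.
* **`DISHRCH` inversion.** The HL7 discipline-specific research code "can
  be equivalent" to `RS-[XX]`, `TDS-[XX]` or `GSO`; the distinguishing
  conditions are not stated, so all three map to `DISHRCH` with fidelity
  `related` and no inverse mapping is offered. Similarly, `GRU(CC)` has
  no stated HL7 equivalence; we map it to `HRESCH` with fidelity
  `broader` and a caution, explicitly as an interpretation.

The registry also records `version_introduced` (v1–v4) for provenance
display only; the historical membership of each early release is not fully
reconstructable from the v4 table's change markers alone.

## The synthetic generators and the oracle

The package tests itself against an independent straight-line
re-implementation of the semantics, `cc_oracle_evaluate()`: one literal
conditional per code, exact term matching, no helpers shared with the
engine. Equivalence is checked on the tuple (status, sorted obligations,
sorted denial rule ids) over:

* the **canonical grid**: every valid profile with at most one secondary
  or at most one requirement (119 profiles, canonical placeholder
  parameters; `TS` gets `12` and `MOR` `2030-01-01` because their
  parameters are typed, `GS` keeps the unknown region `X` to exercise the
  fail-closed branch) crossed with the 1296-point request grid spanning
  every request axis — 154,224 cases, deterministic;
* 2,000 seeded random profile/request pairs with up to two secondaries
  *and* two requirements, covering modifier×gate interactions the
  canonical grid omits.

Property tests add: requirement codes never upgrade a decision
(1,000 seeded trials); health-domain permits nest `DS-X` ⇒ `HMB` ⇒ `GRU`
under identical companion sets (the NDS companion excludes a disease
other than the DS parameter so all three profiles stay satisfiable);
`NRES` permits every grid request with no obligations; and render∘parse is
the identity on every canonical token.

What this shows: the engine implements exactly the semantics stated above,
and those semantics have the expected algebraic structure. What it does
not show: that real-world consent language maps correctly onto code
profiles (a curation problem), that free-text disease parameters align
with any particular ontology, or that the packaged region table matches
any given access agreement. Generator term vocabularies are small and
synthetic; they exercise match/mismatch/absent logic, not terminological
realism.

## Degenerate inputs and numerical choices

No floating-point numerics are involved; determinism is exact. Tie-break
and edge rules: duplicate parameterized instances (e.g. two `NDS`
exclusions) are evaluated per instance; empty request term sets fail
`DS`/`TDS`/`RS` matches and pass `NDS`; `US`/`PS`/`IS` with a missing
requester identifier or approved list fail; decision output ordering is by
dataset id (radix order) so catalog filtering is independent of input
order; all generators restore the caller's RNG state.

## Limitations

The package adjudicates *codes*, not agreements: Data Access Agreement
legal text, authentication and identity (passport-style) handling, FHIR
security-label serialisation, and the full HL7 HCS tag structure beyond
research Purpose-of-Use codes are out of scope. The DUO correspondence is
frozen at the 2021-02-23 snapshot and is not looked up live. Fine-grained
commercial-use distinctions beyond `NPU`/`NCU` (e.g. drug-development vs
diagnostic-development permissions used by some consortia) are not part of
v4 and therefore not modelled.
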