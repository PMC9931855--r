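# consentcodes

Consent-based data use conditions, executable.

Shared genomics datasets and biobank collections carry conditions that come
from the consent their participants gave: *disease-specific research only*,
*not-for-profit use only*, *requestor must publish*, *may derive cell
lines*. The **Consent Codes** vocabulary (v4) records those conditions as
short structured tokens — `HMB(CC)`, `DS-CANCER(CC)`, `NPU`, `TS-24` — so
that data access committees and automated discovery/access systems can act
on them without re-reading consent forms. Repositories such as dbGaP and
the EGA tag datasets this way, and the codes interoperate with the GA4GH
Data Use Ontology (DUO) and the HL7 Healthcare Privacy and Security
Classification System.

`consentcodes` turns the vocabulary into working governance machinery for
data stewards, DAC tooling authors, and biobank informaticians:

* **Registry** — the complete v4 code table (34 codes: 5 primary
  categories, 7 secondary modifiers, 15 requirements, 7 permissions),
  shipped as an auditable TSV with per-code structural metadata
  (`cc_registry()`, `cc_definition()`, `cc_codes()`).
* **Profile parser/validator** — parse token lists into validated consent
  profiles: exactly one primary ("pick only one"), HPOA only on HMB/DS,
  GSO only on genetic resources, `DS-X` + `NDS-X` rejected as
  self-contradictory, and so on (`cc_parse_profile()`,
  `cc_validate_profile()`).
* **Decision engine** — evaluate a structured access request against a
  profile and get `PERMIT` / `PERMIT_WITH_OBLIGATIONS` / `DENY` with
  obligations, granted permissions, machine-stable denial rules and an
  explainable trace (`cc_evaluate()`, `cc_explain()`). Everything fails
  closed.
* **Crosswalks** — fidelity-annotated mappings to DUO terms (snapshot
  2021-02-23) and HL7 research Purpose-of-Use codes, including the three
  documented look-alike cautions and a coverage audit (`cc_to_duo()`,
  `cc_from_duo()`, `cc_to_hl7()`, `cc_coverage_report()`).
* **Catalog filtering + CLI** — read JSON/TSV dataset catalogs, decide
  every entry against a request, write stable decision files
  (`cc_read_catalog()`, `cc_filter_catalog()`, `cc_write_decisions()`;
  `inst/cli/consentcodes.R` exposes `validate`, `explain`, `decide`,
  `map`, `filter`, `audit-coverage`, `fixtures-emit`).
* **Fixtures + oracle** — seeded generators and an independent brute-force
  re-implementation of the semantics used to verify the engine on an
  exhaustive profile × request grid (`cc_random_profile()`,
  `cc_request_grid()`, `cc_oracle_evaluate()`).

## The decision model

A profile is one primary purpose region plus conjunctive modifiers and
conditions. Purpose regions nest: `DS-[X](CC)` ⊂ `HMB(CC)` ⊂ `GRU(CC)` ⊂
`NRES`, with `POA` a separate region that `HPOA` partially carves back
into HMB/DS (health-related ancestry analysis only). A request is permitted
iff

1. its purpose (domain + disease/therapy/research-type terms, matched
   exactly or through an optional term hierarchy) lies inside the primary
   region after applying every secondary modifier (TDS, RS narrow; NDS,
   NMDS, GSO, RUO exclude);
2. every fact gate holds (NPU organization type, NCU commercial purpose,
   GS geography via a region table, TS duration, US/PS/IS approved-entity
   membership);
3. every attestation obligation attached to the profile (PUB, COL, ROR,
   RTN, IRB, BEN, OS, MOR) is agreed to — `MOR-[date]` is also
   cross-checked against a stated publication date;
4. requested biospecimen work is covered by its permission code (CL for
   cell lines, GEN for nucleic-acid extraction);
5. clinical-reference use is requested only where an effective `(CC)` flag
   exists (`(CC)` present and RUO absent).

`NRES` short-circuits all of it: no restrictions at all.

## Worked example

```r
library(consentcodes)

profile <- cc_parse_profile(c("DS-CANCER(CC)", "NPU", "PUB", "IRB"),
                            is_genetic_resource = TRUE)
request <- cc_request(
  "health", disease_terms = "breast cancer",
  requester = cc_requester("not_for_profit", geography = "FR"),
  attestations = c(PUB = TRUE, IRB = TRUE))
matcher <- cc_term_matcher(cc_read_hierarchy(
  system.file("extdata", "example_disease_hierarchy.tsv",
              package = "consentcodes")))

(decision <- cc_evaluate(profile, request, term_matcher = matcher))
#> <decision> PERMIT_WITH_OBLIGATIONS
#>   obligations: PUB, IRB
```

Breast cancer research is permitted on a `DS-CANCER(CC)` resource because
the hierarchy places `BREAST CANCER` under `CANCER`; the decision carries
the publication and ethics-approval obligations. The trace explains every
firing:

```r
cat(cc_explain(decision), sep = "\n")
#> PASS [PURPOSE_PERMITTED] DS-CANCER(CC) (Use of the data/biospecimen must be related to [disease]): requested purpose lies within the permitted region
#> PASS [GATES_MET] : all fact gates met
#> PASS [OBLIGATION_ATTESTED] PUB (Requestor agrees to make results of studies using the data/biospecimen available to the larger scientific community): obligation PUB attested
#> PASS [OBLIGATION_ATTESTED] IRB (Requestor must provide documentation of local IRB/REC approval): obligation IRB attested
#> STATUS: PERMIT_WITH_OBLIGATIONS
```

The same profile denies a for-profit requester who attested nothing, and
says exactly what would change the outcome:

```r
cc_evaluate(profile,
            cc_request("health", disease_terms = "breast cancer",
                       requester = cc_requester("for_profit")),
            term_matcher = matcher)
#> <decision> DENY
#>   obligations: PUB, IRB
#>   denial reasons:
#>     [NPU_ORG] NPU: use is limited to not-for-profit organizations
#>     [OBLIGATION_UNATTESTED] PUB: obligation PUB is not attested; attesting PUB would lift this denial
#>     [OBLIGATION_UNATTESTED] IRB: obligation IRB is not attested; attesting IRB would lift this denial
```

Crosswalk the profile's primary to DUO:

```r
cc_to_duo("DS-CANCER(CC)")
#> <crosswalk> DS -> DUO:0000007 [exact]
```

From a shell, the same machinery:

```sh
Rscript inst/cli/consentcodes.R decide --profile profile.json --request request.json
Rscript inst/cli/consentcodes.R filter --catalog catalog.json --request request.json --out decisions.json
Rscript inst/cli/consentcodes.R map --to duo "HMB(CC)" NPU
```

`decide` exits 0 on permit, 2 on deny, 1 on schema errors, so it composes
in access-automation pipelines.

## Documentation

The methods vignette (`vignettes/consent-governance.Rmd`) describes the
decision semantics, the open interpretation choices (default
methods-development policy, HPOA disease scoping, NRES companions), the
synthetic generators and what the exhaustive tests do and do not show.
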