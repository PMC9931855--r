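{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "consentcodes access request",
  "type": "object",
  "required": ["purpose_domain"],
  "properties": {
    "purpose_domain": { "enum": ["health", "other_biological", "poa"] },
    "disease_terms": { "type": "array", "items": { "type": "string" } },
    "therapy_terms": { "type": "array", "items": { "type": "string" } },
    "research_type_terms": { "type": "array", "items": { "type": "string" } },
    "poa_health_related": { "type": "boolean" },
    "methods_dev": { "enum": ["none", "within_bounds", "general"] },
    "clinical_reference_use": { "type": "boolean" },
    "uses_only_nongenetic_data": { "type": "boolean" },
    "requester": {
      "type": "object",
      "properties": {
        "org_type": { "enum": ["for_profit", "not_for_profit"] },
        "commercial_purpose": { "type": "boolean" },
        "geography": { "type": "string" },
        "user_id": { "type": "string" },
        "project_id": { "type": "string" },
        "institution_id": { "type": "string" },
        "planned_publication_date": { "type": "string", "format": "date" }
      }
    },
    "attestations": {
      "type": "object",
      "additionalProperties": { "type": "boolean" }
    },
    "biospecimen_intents": {
      "type": "array",
      "items": { "enum": ["derive_cell_lines", "extract_nucleic_acids"] }
    },
    "duration_months": { "type": "integer", "minimum": 1 }
  }
}
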