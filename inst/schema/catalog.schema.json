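{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "consentcodes dataset catalog",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["dataset_id", "profile_tokens"],
    "properties": {
      "dataset_id": { "type": "string", "minLength": 1 },
      "title": { "type": "string" },
      "resource_kind": {
        "type": "array",
        "items": { "enum": ["data", "biospecimen"] },
        "minItems": 1,
        "uniqueItems": true
      },
      "is_genetic_resource": { "type": "boolean" },
      "profile_tokens": {
        "type": "array",
        "items": { "type": "string", "minLength": 1 },
        "minItems": 1
      },
      "approved_entities": {
        "type": "object",
        "properties": {
          "users": { "type": "array", "items": { "type": "string" } },
          "projects": { "type": "array", "items": { "type": "string" } },
          "institutions": { "type": "array", "items": { "type": "string" } }
        }
      }
    }
  }
}
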