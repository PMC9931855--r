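{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "consentcodes decision",
  "type": "object",
  "required": ["status"],
  "properties": {
    "status": { "enum": ["PERMIT", "PERMIT_WITH_OBLIGATIONS", "DENY"] },
    "obligations": { "type": "array", "items": { "type": "string" } },
    "granted_permissions": { "type": "array", "items": { "type": "string" } },
    "denial_reasons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule", "code", "message"],
        "properties": {
          "rule": { "type": "string" },
          "code": { "type": "string" },
          "message": { "type": "string" }
        }
      }
    },
    "trace": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule", "outcome"],
        "properties": {
          "rule": { "type": "string" },
          "code": { "type": "string" },
          "outcome": { "enum": ["pass", "fail", "info"] },
          "message": { "type": "string" }
        }
      }
    }
  }
}
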