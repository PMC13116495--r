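{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Per-patient nursing surveillance recommendation document",
  "type": "object",
  "required": ["patient_id", "risk", "recommendations"],
  "properties": {
    "patient_id": { "type": "string" },
    "risk": { "enum": ["high", "low"] },
    "recommendations": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["action", "evidence", "rationale"],
        "properties": {
          "action": {
            "type": "array",
            "items": { "type": "string" },
            "minItems": 1
          },
          "action_id": { "type": "integer", "minimum": 1, "maximum": 12 },
          "evidence": { "type": "string" },
          "evidence_feature": { "type": "string" },
          "evidence_value": { "type": ["number", "null"] },
          "rationale": { "type": "string" }
        }
      }
    }
  }
}
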