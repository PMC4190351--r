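{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/conqual/review-schema.json",
  "title": "ConQual review document",
  "type": "object",
  "required": ["title", "population", "phenomena_of_interest", "context",
               "studies", "findings", "synthesised_findings"],
  "properties": {
    "title": {"type": "string"},
    "population": {"type": "string"},
    "phenomena_of_interest": {"type": "string"},
    "context": {"type": "string"},
    "studies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "appraisal"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "citation": {"type": "string"},
          "appraisal": {
            "type": "object",
            "required": ["q1", "q2", "q3", "q4", "q5"],
            "properties": {
              "q1": {"$ref": "#/$defs/response"},
              "q2": {"$ref": "#/$defs/response"},
              "q3": {"$ref": "#/$defs/response"},
              "q4": {"$ref": "#/$defs/response"},
              "q5": {"$ref": "#/$defs/response"}
            },
            "additionalProperties": false
          }
        }
      }
    },
    "findings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "study_id", "credibility"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "study_id": {"type": "string", "minLength": 1},
          "statement": {"type": "string"},
          "illustration": {"type": "string"},
          "credibility": {"enum": ["Unequivocal", "Equivocal", "Unsupported"]}
        }
      }
    },
    "synthesised_findings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "finding_ids"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "statement": {"type": "string"},
          "finding_ids": {
            "type": "array",
            "items": {"type": "string", "minLength": 1},
            "minItems": 1,
            "uniqueItems": true
          },
          "research_type": {"type": "string"}
        }
      }
    }
  },
  "$defs": {
    "response": {"enum": ["yes", "no", "unclear"]}
  }
}
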