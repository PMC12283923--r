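{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "causalor analysis report",
  "type": "object",
  "required": ["descriptives", "estimates", "provenance"],
  "properties": {
    "descriptives": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "test", "p_raw", "p_adjusted"],
        "properties": {
          "variable": {"type": "string"},
          "test": {"type": "string"},
          "p_raw": {"type": ["number", "null"]},
          "p_adjusted": {"type": ["number", "null"]}
        }
      }
    },
    "estimates": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "oneOf": [
            {
              "required": ["method", "psi1", "psi0", "or", "n"],
              "properties": {
                "method": {"enum": ["GC", "IPTW", "TMLE", "TMLE_SL"]},
                "psi1": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
                "psi0": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
                "or": {"type": "number", "exclusiveMinimum": 0},
                "n": {"type": "integer", "minimum": 2},
                "ci": {
                  "type": "object",
                  "required": ["lower", "upper", "level", "construction"],
                  "properties": {
                    "lower": {"type": "number"},
                    "upper": {"type": "number"},
                    "level": {"type": "number"},
                    "construction": {"enum": ["bootstrap", "influence_curve"]}
                  }
                }
              }
            },
            {
              "required": ["method", "failed", "message"],
              "properties": {"failed": {"const": true}}
            }
          ]
        }
      }
    },
    "balance": {"type": ["array", "null"]},
    "sensitivity": {"type": ["array", "null"]},
    "guards": {"type": "object"},
    "provenance": {
      "type": "object",
      "required": ["package_version", "seed", "n", "config_hash"],
      "properties": {
        "package_version": {"type": "string"},
        "seed": {"type": "integer"},
        "n": {"type": "integer"},
        "config_hash": {"type": "string"},
        "timestamp": {"type": "string"}
      }
    }
  }
}
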