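{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ducg-model",
  "description": "Causality-graph model: typed variables, weighted causal arcs with causal-function matrices, logic gates, priors and exclusivity categories. null marks an unknown parameter (distinct from an explicit 0).",
  "type": "object",
  "required": ["variables", "arcs", "gates", "priors", "categories"],
  "properties": {
    "format": { "const": "ducg-model" },
    "version": { "type": "integer" },
    "variables": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "n_states"],
        "properties": {
          "id": { "type": "string", "pattern": "^[BXGD][0-9]+$" },
          "n_states": { "type": "integer", "minimum": 1 },
          "labels": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "arcs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["parent", "child", "a"],
        "properties": {
          "parent": { "type": "string" },
          "child": { "type": "string" },
          "r": { "type": "number", "minimum": 0 },
          "a": {
            "description": "dense matrix, rows = child states, columns = parent states; null = unknown",
            "type": "array",
            "items": {
              "type": "array",
              "items": { "type": ["number", "null"] }
            }
          }
        }
      }
    },
    "gates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gate", "inputs", "state_exprs"],
        "properties": {
          "gate": { "type": "string" },
          "inputs": { "type": "array", "items": { "type": "string" } },
          "state_exprs": {
            "description": "nonzero state -> sum of products of input-state literals; state 0 is the implicit remnant",
            "type": "object",
            "additionalProperties": {
              "type": "array",
              "items": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["var", "state"],
                  "properties": {
                    "var": { "type": "string" },
                    "state": { "type": "integer", "minimum": 0 }
                  }
                }
              }
            }
          }
        }
      }
    },
    "priors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "b"],
        "properties": {
          "variable": { "type": "string" },
          "b": { "type": "array", "items": { "type": ["number", "null"] } }
        }
      }
    },
    "categories": {
      "type": "object",
      "properties": {
        "exclusive": {
          "type": "array",
          "items": { "type": "array", "items": { "type": "string" } }
        },
        "concurrent": { "type": "array", "items": { "type": "string" } }
      }
    },
    "meta": { "type": "object" }
  }
}
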