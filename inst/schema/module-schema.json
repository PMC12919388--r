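{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "gestsynth-module-schema-v1",
  "title": "gestsynth clinical module definition (dialect v1)",
  "description": "A named directed graph of typed clinical states with probabilistic transitions. Time advances in whole weeks via Delay states. This dialect is self-defined and is not byte-compatible with other state-machine simulators.",
  "type": "object",
  "required": ["name", "initial", "states"],
  "properties": {
    "name": { "type": "string", "minLength": 1 },
    "initial": {
      "type": "string",
      "description": "Name of the unique Initial state."
    },
    "states": {
      "type": "object",
      "description": "Map of state name to state object.",
      "additionalProperties": { "$ref": "#/definitions/state" }
    }
  },
  "definitions": {
    "state": {
      "type": "object",
      "required": ["kind"],
      "properties": {
        "kind": {
          "enum": ["Initial", "Simple", "Delay", "Encounter",
                   "ConditionOnset", "ConditionEnd", "Procedure",
                   "Observation", "SetAttribute", "Death", "Terminal"]
        },
        "codes": {
          "type": "array",
          "items": { "$ref": "#/definitions/codedConcept" },
          "description": "Required (>= 1 item) for Encounter, ConditionOnset, ConditionEnd, Procedure and Observation states; optional cause code for Death."
        },
        "delay": {
          "description": "Delay states only: whole weeks, either a fixed non-negative integer or {low, high} drawn uniformly.",
          "oneOf": [
            { "type": "integer", "minimum": 0 },
            {
              "type": "object",
              "required": ["low", "high"],
              "properties": {
                "low": { "type": "integer", "minimum": 0 },
                "high": { "type": "integer", "minimum": 0 }
              }
            }
          ]
        },
        "attribute": { "type": "string" },
        "value": {},
        "transition": {
          "$ref": "#/definitions/transition",
          "description": "Required for every kind except Terminal."
        }
      }
    },
    "codedConcept": {
      "type": "object",
      "required": ["system", "code"],
      "properties": {
        "system": { "enum": ["SNOMED-CT", "CIE-10", "CUPS"] },
        "code": { "type": "string", "minLength": 1 },
        "display": { "type": "string" }
      }
    },
    "transition": {
      "type": "object",
      "required": ["mode", "branches"],
      "properties": {
        "mode": { "enum": ["Direct", "Distributed", "Conditional"] },
        "branches": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/branch" },
          "description": "Direct: exactly one branch with probability 1. Distributed: probabilities sum to 1 (tolerance 1e-9). Conditional: evaluated in order; the final branch must omit its predicate (catch-all)."
        }
      }
    },
    "branch": {
      "type": "object",
      "required": ["target"],
      "properties": {
        "target": { "type": "string" },
        "probability": { "type": "number", "minimum": 0, "maximum": 1 },
        "predicate": {
          "type": "object",
          "required": ["attribute", "op"],
          "properties": {
            "attribute": { "type": "string" },
            "op": { "enum": ["eq", "ne", "exists", "absent"] },
            "value": {}
          }
        }
      }
    }
  }
}
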