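{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "trackmsd run report",
  "type": "object",
  "required": ["lines", "provenance"],
  "properties": {
    "lines": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": {
        "type": "object",
        "required": ["line_id", "condition", "n_cells", "speed_mean",
                     "speed_sd", "displacement_mean", "displacement_sd",
                     "alpha", "alpha_ci", "regime"],
        "properties": {
          "line_id": {"type": "string"},
          "condition": {"enum": ["control", "patient", "synthetic"]},
          "n_cells": {"type": "integer", "minimum": 1},
          "speed_mean": {"type": "number", "minimum": 0},
          "speed_sd": {"type": "number", "minimum": 0},
          "displacement_mean": {"type": "number", "minimum": 0},
          "displacement_sd": {"type": "number", "minimum": 0},
          "alpha": {"type": "number"},
          "alpha_stderr": {"type": ["number", "null"], "minimum": 0},
          "alpha_ci": {
            "type": "array", "items": {"type": "number"},
            "minItems": 2, "maxItems": 2
          },
          "r_squared": {"type": "number", "minimum": 0, "maximum": 1},
          "n_lags_used": {"type": "integer", "minimum": 3},
          "regime": {"enum": ["sub_diffusive", "brownian",
                              "super_diffusive", "ballistic_like"]}
        }
      }
    },
    "group_decision": {
      "type": ["object", "null"],
      "required": ["control_mean_alpha", "control_alphas", "patient_ci",
                   "different", "rule"],
      "properties": {
        "control_mean_alpha": {"type": "number"},
        "control_alphas": {"type": "array", "items": {"type": "number"}},
        "patient_ci": {"type": "array"},
        "different": {"type": "array", "items": {"type": "boolean"}},
        "rule": {"type": "string"}
      }
    },
    "speed_test": {
      "type": ["object", "null"],
      "required": ["statistic", "df", "p_value", "test_kind"],
      "properties": {
        "statistic": {"type": "number"},
        "df": {"type": "number", "exclusiveMinimum": 0},
        "p_value": {"type": "number", "minimum": 0, "maximum": 1},
        "test_kind": {"enum": ["paired", "unpaired_welch"]}
      }
    },
    "provenance": {
      "type": "object",
      "required": ["package_version", "r_version", "seed",
                   "max_lag_fraction", "min_points", "test_kind",
                   "timestamp"]
    }
  }
}
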