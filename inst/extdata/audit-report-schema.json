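{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ohcaudit audit report",
  "description": "Structure of the JSON emitted by audit_to_json(); checked structurally by validate_audit_json().",
  "type": "object",
  "required": ["cascade", "goals", "time_metrics", "attainment", "verdicts",
               "lives_saved", "overall_survival", "provenance"],
  "properties": {
    "cascade": {
      "type": "object",
      "required": ["n_input", "study_exclusions", "n_included",
                   "recognizability_exclusions", "n_recognizable",
                   "n_recognized_overall", "n_recognized",
                   "dacpr_exclusions", "n_dacpr_available"],
      "properties": {
        "n_input": {"type": "integer", "minimum": 0},
        "study_exclusions": {
          "type": "object",
          "required": ["ALIVE_DURING_CALL", "MISSING_AUDIO"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "n_included": {"type": "integer", "minimum": 0},
        "recognizability_exclusions": {
          "type": "object",
          "required": ["CPR_IN_PROGRESS", "THIRD_PARTY", "HYSTERICAL",
                       "HANG_UP", "LANGUAGE", "OTHER"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "n_recognizable": {"type": "integer", "minimum": 0},
        "n_recognized_overall": {"type": "integer", "minimum": 0},
        "n_recognized": {"type": "integer", "minimum": 0},
        "dacpr_exclusions": {
          "type": "object",
          "required": ["CANNOT_MOVE", "REFUSES", "HANG_UP",
                       "NOT_WITH_PATIENT", "OTHER"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "n_dacpr_available": {"type": "integer", "minimum": 0}
      }
    },
    "goals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["goal_id", "measure", "numerator", "denominator", "pct"],
        "properties": {
          "goal_id": {"type": ["integer", "null"]},
          "measure": {"type": "string"},
          "numerator": {"type": "integer", "minimum": 0},
          "denominator": {"type": "integer", "minimum": 0},
          "pct": {"type": ["number", "null"]},
          "pct_rounded": {"type": ["integer", "null"]},
          "target_pct": {"type": ["number", "null"]},
          "met": {"type": "boolean"},
          "undefined": {"type": "boolean"}
        }
      }
    },
    "time_metrics": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "n_stage", "n_with_time", "n_missing"],
        "properties": {
          "goal_id": {"type": "integer"},
          "variable": {"type": "string"},
          "n_stage": {"type": "integer", "minimum": 0},
          "n_applicable": {"type": "integer", "minimum": 0},
          "n_with_time": {"type": "integer", "minimum": 0},
          "n_missing": {"type": "integer", "minimum": 0},
          "median_s": {"type": ["number", "null"]},
          "q1_s": {"type": ["number", "null"]},
          "q3_s": {"type": ["number", "null"]}
        }
      }
    },
    "attainment": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "threshold_s", "n", "pct"],
        "properties": {
          "variable": {"type": "string"},
          "threshold_s": {"type": "number", "exclusiveMinimum": 0},
          "n": {"type": "integer", "minimum": 0},
          "pct": {"type": ["number", "null"]},
          "pct_rounded": {"type": ["integer", "null"]}
        }
      }
    },
    "verdicts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["goal_id", "variable", "median_s"],
        "properties": {
          "met_high": {"type": "boolean"},
          "met_minimal": {"type": "boolean"}
        }
      }
    },
    "lives_saved": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["time_field", "threshold_s", "p_met", "p_not_met",
                     "n_not_met", "raw", "additional_lives"],
        "properties": {
          "raw": {"type": "number"},
          "additional_lives": {"type": "integer", "minimum": 0},
          "negative_effect": {"type": "boolean"}
        }
      }
    },
    "overall_survival": {
      "type": "object",
      "required": ["numerator", "denominator", "pct"]
    },
    "provenance": {
      "type": "object",
      "required": ["n_input", "input_hash", "package_version"]
    }
  }
}
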