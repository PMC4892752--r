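{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "audbat cohort configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "n_controls": {"type": "integer", "minimum": 0},
    "subgroups": {
      "type": "object",
      "properties": {
        "SV": {"type": "integer", "minimum": 0},
        "NFV": {"type": "integer", "minimum": 0},
        "LV": {"type": "integer", "minimum": 0}
      }
    },
    "deficit_profiles": {
      "type": "object",
      "description": "per subtype: named per-task shifts in control-SD units",
      "additionalProperties": {"type": "object"}
    },
    "latent_shifts": {
      "type": "object",
      "description": "per subtype: [semantic, repetition] latent shifts",
      "additionalProperties": {
        "type": "array", "items": {"type": "number"},
        "minItems": 2, "maxItems": 2
      }
    },
    "cpm_p2_r": {"type": "number", "exclusiveMinimum": -1,
                 "exclusiveMaximum": 1},
    "outcome_model": {"type": "object"},
    "age_mean": {"type": "number"},
    "age_sd": {"type": "number", "minimum": 0},
    "observer_beta": {"type": "number", "exclusiveMinimum": 0},
    "observer_lapse": {"type": "number", "minimum": 0, "maximum": 0.1}
  }
}
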