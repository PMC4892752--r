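{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "audbat analysis report",
  "type": "object",
  "required": ["seed", "n_subjects", "groups", "transformed_tasks",
               "group", "singlecase"],
  "properties": {
    "seed": {"type": "number"},
    "n_subjects": {"type": "integer", "minimum": 1},
    "groups": {"type": "object"},
    "transformed_tasks": {"type": "array", "items": {"type": "string"}},
    "group": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["task", "t", "df", "p", "significant_bonferroni"]
      }
    },
    "subtype_omnibus": {"type": "array"},
    "singlecase": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["patient", "task", "t", "p", "z",
                     "impaired_bonferroni"]
      }
    },
    "covariates": {"type": "array", "items": {"type": "string"}},
    "svm": {"type": "object"},
    "factors": {"type": "object"},
    "factor_corr": {"type": "array"},
    "duration_corr": {"type": "array"},
    "hearing_corr": {"type": "array"},
    "digitspan_corr": {"type": "array"}
  }
}
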