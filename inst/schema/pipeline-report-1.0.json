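{
  "schema_version": "1.0",
  "title": "bdrprs pipeline report",
  "required_fields": {
    "schema_version": "string",
    "weight_table_summary": "object",
    "cohort_summary": "object",
    "association_results": "object",
    "software_version": "string",
    "config_echo": "object",
    "seed": "integer"
  },
  "cohort_summary_fields": {
    "n": "integer",
    "bdr_mean": "number|null",
    "bdr_sd": "number|null",
    "frac_ge_12": "number in [0,1]",
    "frac_ge_8": "number in [0,1]|null",
    "prs_raw_mean": "number",
    "prs_raw_sd": "number"
  },
  "association_result_fields": {
    "model": "linear|logistic",
    "outcome": "string",
    "estimate": "number",
    "se": "number",
    "p_value": "number in (0,1]",
    "n": "integer",
    "covariate_estimates": "object",
    "formula": "string naming the covariate set"
  }
}
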