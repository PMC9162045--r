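{
  "name": "general-cvd-office-bmi",
  "version": 1,
  "description": "Sex-specific office-based (non-laboratory, BMI) general cardiovascular disease 10-year risk function. risk = 1 - baseline_survival ^ exp(LP - mean_lp), LP = b_age*log(age) + b_bmi*log(bmi) + b_sbp*log(sbp) (treated or untreated coefficient by antihypertensive medication status) + b_smoker*smoker + b_diabetes*diabetes.",
  "derivation_range_years": [30, 74],
  "female": {
    "log_age": 2.72107,
    "log_bmi": 0.51125,
    "log_sbp_untreated": 2.81291,
    "log_sbp_treated": 2.88267,
    "smoker": 0.61868,
    "diabetes": 0.77763,
    "baseline_survival": 0.94833,
    "mean_lp": 26.0145
  },
  "male": {
    "log_age": 3.11296,
    "log_bmi": 0.79277,
    "log_sbp_untreated": 1.85508,
    "log_sbp_treated": 1.92672,
    "smoker": 0.70953,
    "diabetes": 0.53160,
    "baseline_survival": 0.88431,
    "mean_lp": 23.9388
  }
}
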