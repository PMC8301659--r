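{
  "comparisons": [
    {
      "trial_id": "actt1_prelim",
      "outcome": "time_to_recovery",
      "subgroup": null,
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.32, "ci_lower": 1.12, "ci_upper": 1.55, "level": 0.95, "n1": 538, "n2": 521},
      "notes": "recovery rate ratio with 95% CI from the preliminary trial report; t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "actt1_prelim",
      "outcome": "mortality_day14",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 538, "y1": 32, "n2": 521, "y2": 54},
      "notes": "deaths per arm at the preliminary data cut"
    },
    {
      "trial_id": "actt1_final",
      "outcome": "time_to_recovery",
      "subgroup": null,
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.29, "ci_lower": 1.12, "ci_upper": 1.49, "level": 0.95, "n1": 541, "n2": 521},
      "notes": "recovery rate ratio with 95% CI from the final trial report; t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "actt1_final",
      "outcome": "mortality_day15",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 541, "y1": 35, "n2": 521, "y2": 61},
      "notes": "deaths by day 15 per arm from the final trial report (transcription approximate)"
    },
    {
      "trial_id": "actt1_final",
      "outcome": "mortality_day29",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 541, "y1": 59, "n2": 521, "y2": 77},
      "notes": "deaths by day 29 per arm from the final trial report"
    },
    {
      "trial_id": "wang",
      "outcome": "time_to_improvement",
      "subgroup": null,
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.23, "ci_lower": 0.87, "ci_upper": 1.75, "level": 0.95, "n1": 158, "n2": 78},
      "notes": "time-to-clinical-improvement hazard ratio with 95% CI; t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "wang",
      "outcome": "mortality_day28",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 158, "y1": 22, "n2": 78, "y2": 10},
      "notes": "28-day deaths per arm"
    },
    {
      "trial_id": "wang",
      "outcome": "time_to_improvement",
      "subgroup": "early_treatment",
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.52, "ci_lower": 0.95, "ci_upper": 2.43, "level": 0.95, "n1": 71, "n2": 47},
      "notes": "patients treated within 10 days of symptom onset; hazard ratio with 95% CI; t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "wang",
      "outcome": "mortality_day28",
      "subgroup": "early_treatment",
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 71, "y1": 8, "n2": 47, "y2": 7},
      "notes": "28-day deaths in the early-treatment subgroup"
    },
    {
      "trial_id": "gs5773",
      "outcome": "clinical_improvement_day14",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_higher",
      "payload": {"n1": 200, "y1": 129, "n2": 197, "y2": 107},
      "notes": "patients with >= 2-point improvement on the 7-point ordinal scale by day 14; 5-day course vs 10-day course (no placebo arm)"
    },
    {
      "trial_id": "gs5773",
      "outcome": "mortality_day14",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 200, "y1": 16, "n2": 197, "y2": 21},
      "notes": "deaths by day 14; 5-day course vs 10-day course"
    },
    {
      "trial_id": "gs5774",
      "outcome": "clinical_status_day11",
      "subgroup": "5day_vs_soc",
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.65, "ci_lower": 1.09, "ci_upper": 2.48, "level": 0.95, "n1": 199, "n2": 200},
      "notes": "proportional-odds ratio for better day-11 clinical status, 5-day remdesivir vs standard of care; t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "gs5774",
      "outcome": "clinical_status_day11",
      "subgroup": "10day_vs_soc",
      "outcome_kind": "ratio_ci",
      "direction": "benefit_higher",
      "payload": {"ratio": 1.31, "ci_lower": 0.88, "ci_upper": 1.95, "level": 0.95, "n1": 197, "n2": 200},
      "notes": "proportional-odds ratio for better day-11 clinical status, 10-day remdesivir vs standard of care (transcription approximate); t reconstructed from the log-ratio Wald CI"
    },
    {
      "trial_id": "solidarity",
      "outcome": "inhospital_mortality",
      "subgroup": null,
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 2743, "y1": 301, "n2": 2708, "y2": 303},
      "notes": "in-hospital deaths, remdesivir vs standard of care (interim report)"
    },
    {
      "trial_id": "solidarity",
      "outcome": "inhospital_mortality",
      "subgroup": "no_ventilation",
      "outcome_kind": "binary_counts",
      "direction": "benefit_lower",
      "payload": {"n1": 2489, "y1": 192, "n2": 2475, "y2": 219},
      "notes": "in-hospital deaths among patients not on mechanical ventilation at entry (transcription approximate)"
    }
  ]
}
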