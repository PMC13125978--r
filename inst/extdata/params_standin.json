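{
  "names": ["bc_base_const", "bc_base_logt", "bc_base_sqrt", "oth_base_const", "oth_base_logt", "oth_base_sqrt", "bc_size", "bc_nodes", "bc_age1", "bc_age2", "bc_grade2", "bc_grade3", "bc_er_neg", "bc_pr_neg", "bc_her2_pos", "bc_ki67_pos", "oth_age1", "oth_age2", "oth_smoking", "bc_chemo", "bc_hormone", "bc_trastuzumab", "bc_bisphosphonates", "bc_radio", "bc_screen", "oth_heart_dose"],
  "values": [-6.2, 1, 0.5, -6.6, 1.1, 0.3, 0.75, 0.7, 0.2, 1.2, 0.45, 0.95, 0.35, 0.25, 0.3, 0.2, 0.3, 5.8, 0.45, -0.35, -0.3, -0.3, -0.1, -0.1, -0.25, 0.05],
  "groups": ["baseline_bc", "baseline_bc", "baseline_bc", "baseline_oth", "baseline_oth", "baseline_oth", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_bc", "covariate_oth", "covariate_oth", "covariate_oth", "treatment_effect", "treatment_effect", "treatment_effect", "treatment_effect", "treatment_effect", "treatment_effect", "treatment_effect"],
  "basis": {
    "bc": [0, 0.5],
    "oth": [0, 0.5]
  },
  "mandatory": ["age", "size_mm", "nodes", "grade", "er_positive"],
  "provenance": {
    "note": "documented stand-in coefficient set: plausible magnitudes, clinically correct signs; not the published tool's coefficients"
  }
}
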