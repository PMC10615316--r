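[
  {"name": "mass_action", "pattern": "C*M",
   "note": "monomial rate C * prod(x_i^k_i); includes constant sources"},
  {"name": "michaelis_menten", "pattern": "C*Xi/(1 + K*Xi)",
   "note": "saturating enzyme kinetics / Monod growth on substrate Xi"},
  {"name": "monod_growth", "pattern": "C*Xi*Xj/(1 + K*Xj)",
   "note": "biomass Xi times Monod saturation in substrate Xj"},
  {"name": "hill_activation", "pattern": "C*Xi^n/(1 + K*Xi^n)", "n": [2, 6],
   "note": "cooperative activation with Hill exponent n"},
  {"name": "hill_repression", "pattern": "C/(1 + K*Xi^n)", "n": [2, 6],
   "note": "cooperative repression with Hill exponent n"},
  {"name": "hill_modulated_uptake", "pattern": "C*Xi*Xj/(1 + K*Xj^n)",
   "n": [2, 6],
   "note": "bilinear uptake modulated by a Hill term in Xj (glycolytic PFK)"},
  {"name": "saturating_feedback", "pattern": "C*Xi^2/(1 + K*Xi)",
   "note": "saturating feedback in differentiation/renewal rates"},
  {"name": "shared_capacity_degradation", "pattern": "C*Xi/(1 + K*Xi + L*Xj)",
   "note": "first-order removal saturated by the joint load of Xi and Xj"},
  {"name": "qssm_modulation", "pattern": "C*Xi*Xj^2/(K*Xj + Xi)",
   "note": "quorum-sensing modulation of a bilinear interaction"},
  {"name": "logistic", "pattern": "C*Xi*(1 - Xi/K)",
   "note": "logistic growth; expands to the mass-action pair C*Xi - (C/K)*Xi^2"}
]
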