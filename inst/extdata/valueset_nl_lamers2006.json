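{
  "name": "NL",
  "source": "Lamers LM, McDonnell J, Stalmeier PFM, Krabbe PFM, Busschbach JJV. The Dutch tariff: results and arguments for an effective design for national EQ-5D valuation studies. Health Economics 2006;15(10):1121-1132.",
  "constant": 1.0,
  "decrements": {
    "mobility":           {"2": 0.036, "3": 0.161},
    "self_care":          {"2": 0.082, "3": 0.152},
    "usual_activities":   {"2": 0.032, "3": 0.057},
    "pain_discomfort":    {"2": 0.086, "3": 0.329},
    "anxiety_depression": {"2": 0.124, "3": 0.325}
  },
  "extras": [
    {"predicate": "any_level_gt1", "value": 0.071},
    {"predicate": "any_level_3",   "value": 0.234}
  ]
}
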