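{
  "name": "UK",
  "source": "Dolan P. Modeling valuations for EuroQol health states. Medical Care 1997;35(11):1095-1108 (MVH time-trade-off tariff, A1 model).",
  "constant": 1.0,
  "decrements": {
    "mobility":           {"2": 0.069, "3": 0.314},
    "self_care":          {"2": 0.104, "3": 0.214},
    "usual_activities":   {"2": 0.036, "3": 0.094},
    "pain_discomfort":    {"2": 0.123, "3": 0.386},
    "anxiety_depression": {"2": 0.071, "3": 0.236}
  },
  "extras": [
    {"predicate": "any_level_gt1", "value": 0.081},
    {"predicate": "any_level_3",   "value": 0.269}
  ]
}
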