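{
  "legitimate": {
    "completion_meanlog": 2.708,
    "completion_sdlog": 0.35,
    "completion_min": 10,
    "night_prob": 0.05,
    "hidden_prob": 0,
    "template_reuse_prob": 0,
    "n_templates": 0,
    "zip_mismatch_prob": 0,
    "nonus_prob": 0,
    "facility_unknown_prob": 0,
    "referral_unknown_prob": 0,
    "straightline_prob": 0
  },
  "satisficer": {
    "completion_meanlog": 1.946,
    "completion_sdlog": 0.15,
    "completion_min": 5,
    "night_prob": 0.1,
    "hidden_prob": 0,
    "template_reuse_prob": 0,
    "n_templates": 0,
    "zip_mismatch_prob": 0,
    "nonus_prob": 0,
    "facility_unknown_prob": 0,
    "referral_unknown_prob": 0,
    "straightline_prob": 0.6
  },
  "bot": {
    "completion_meanlog": 0,
    "completion_sdlog": 0.4,
    "completion_min": 0.2,
    "night_prob": 0.9,
    "hidden_prob": 1,
    "template_reuse_prob": 0,
    "n_templates": 0,
    "zip_mismatch_prob": 0.3,
    "nonus_prob": 0.4,
    "facility_unknown_prob": 0.7,
    "referral_unknown_prob": 0.7,
    "straightline_prob": 0.3
  },
  "farm": {
    "completion_meanlog": 1.792,
    "completion_sdlog": 0.5,
    "completion_min": 2,
    "night_prob": 0.8,
    "hidden_prob": 0,
    "template_reuse_prob": 0.65,
    "n_templates": 8,
    "zip_mismatch_prob": 0.5,
    "nonus_prob": 0.35,
    "facility_unknown_prob": 0.6,
    "referral_unknown_prob": 0.5,
    "straightline_prob": 0.2
  }
}
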