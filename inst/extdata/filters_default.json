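{
  "allowed_phases": ["I", "I_II", "II", "II_III", "III"],
  "allowed_statuses": ["recruiting", "active_not_recruiting", "enrolling_by_invitation"],
  "study_type": "interventional",
  "exclude_net": true,
  "exclude_non_therapeutic": true
}
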