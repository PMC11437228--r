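# SYNTHETIC coefficient set for the MICA-style logistic risk model.
# These are NOT the published calculator coefficients; they exist so the
# model plumbing can be exercised and configured. Transcribe the published
# values into a file of this shape to use the real calculator.
intercept: -5.25
coefficients:
  age_years: 0.02
  asa_class: 0.65
  creatinine_elevated: 0.80
  functional_dependent: 1.00
  procedure_vascular: 1.10
  procedure_orthopedic: 0.45
  procedure_abdominal: 0.70
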