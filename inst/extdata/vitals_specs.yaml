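# Clinical plausibility ranges for the default vitals panel.
# Values outside BOTH the cohort box-plot fence and these ranges are
# treated as artefacts and replaced by the cohort median.
HR:
  clinical_low: 20
  clinical_high: 250
SBP:
  clinical_low: 40
  clinical_high: 280
RR:
  clinical_low: 4
  clinical_high: 70
Temp:
  clinical_low: 30
  clinical_high: 43
  unit_maps:
    F:              # Fahrenheit charted values -> Celsius
      scale: 0.5556
      offset: -17.78
SpO2:
  clinical_low: 40
  clinical_high: 100
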