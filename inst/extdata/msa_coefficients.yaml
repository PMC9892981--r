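# Default sex-specific MSA regression coefficients (years output).
# Keys: intercept plus one multiplier per predictor.
#   wc  - waist circumference (cm)
#   pp  - pulse pressure = sbp - dbp (mmHg)
#   fbs - fasting blood sugar (mg/dL)
#   tg  - triglycerides (mg/dL)
#   hdl - HDL cholesterol (mg/dL); protective, negative coefficient
#   ca  - chronological age (years)
male:
  intercept: -82.688
  wc: 0.779
  pp: 0.227
  fbs: 0.269
  tg: 0.085
  hdl: -0.481
  ca: 0.857
female:
  intercept: -60.340
  wc: 0.613
  pp: 0.371
  fbs: 0.328
  tg: 0.100
  hdl: -0.385
  ca: 0.538
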