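IHD:
  form: cloglog
  coefficients:
    intercept: -5.8
    age_current: 0.02
  second_event: no
MI:
  form: cloglog
  coefficients:
    intercept: -6.0
    age_current: 0.025
    hist_MI: 0.5
    hist_STROKE: 0.3
  second_event: yes
STROKE:
  form: cloglog
  coefficients:
    intercept: -6.6
    age_current: 0.03
    hist_STROKE: 0.6
    hist_MI: 0.3
  second_event: yes
CHF:
  form: cloglog
  coefficients:
    intercept: -6.4
    age_current: 0.03
    hist_MI: 0.6
  second_event: no
BLINDNESS:
  form: cloglog
  coefficients:
    intercept: -6.2
    year: 0.02
  second_event: no
AMPUTATION:
  form: cloglog
  coefficients:
    intercept: -6.8
    hist_ULCER: 1.0
  second_event: yes
RENAL_FAILURE:
  form: cloglog
  coefficients:
    intercept: -6.6
    diabetes_duration: 0.02
  second_event: no
ULCER:
  form: cloglog
  coefficients:
    intercept: -6.3
    diabetes_duration: 0.015
  second_event: no
DEATH:
  form: cloglog
  coefficients:
    intercept: -6.7
    age_current: 0.04
    hist_MI: 0.5
    hist_STROKE: 0.5
    hist_CHF: 0.6
    hist_RENAL_FAILURE: 0.8
    new_MI: 0.8
    new_STROKE: 0.8
  second_event: no
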