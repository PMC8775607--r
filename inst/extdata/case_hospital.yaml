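classes:
  outpatient:
    class: outpatient
    share: 0.724527547245
    arrival_model: renewal
    p_male: 0.5
    p_male_dvt: 0.428571428571
    arrival_spec:
      kind: exponential
      mean: 6.295524908528
  inpatient:
    class: inpatient
    share: 0.199780021998
    arrival_model: renewal
    p_male: 0.5
    p_male_dvt: 0.428571428571
    arrival_spec:
      kind: exponential
      mean: 24.051612903226
  emergency:
    class: emergency
    share: 0.075692430757
    arrival_model: renewal
    p_male: 0.5
    p_male_dvt: 0.428571428571
    arrival_spec:
      kind: exponential
      mean: 59.018469656992
exams:
  abdomen:
    name: abdomen
    share: 0.38
    slot_rule: fixed20
    sex_constraint: none
    service_spec:
      kind: weibull_scaled
      offset: 8.0
      scale: 8.0
      shape: 1.6
  liver:
    name: liver
    share: 0.12
    slot_rule: fixed40
    sex_constraint: none
    service_spec:
      kind: weibull_scaled
      offset: 20.0
      scale: 13.5
      shape: 1.8
  dvt:
    name: dvt
    share: 0.07
    slot_rule: dvt_split
    sex_constraint: same_sex_tech
    service_spec:
      kind: mixture
      weights:
      - 0.7
      - 0.3
      components:
      - kind: weibull_scaled
        offset: 8.0
        scale: 8.0
        shape: 1.6
      - kind: weibull_scaled
        offset: 18.0
        scale: 13.5
        shape: 1.8
  prostate:
    name: prostate
    share: 0.04
    slot_rule: fixed20
    sex_constraint: male_tech_only
    service_spec:
      kind: mixture
      weights:
      - 0.485
      - 0.424
      - 0.091
      components:
      - kind: beta_scaled
        offset: 3.0
        scale: 7.0
        shape1: 1.9
        shape2: 1.16
      - kind: weibull_scaled
        offset: 10.0
        scale: 3.46
        shape: 1.23
      - kind: weibull_scaled
        offset: 20.0
        scale: 6.99
        shape: 1.29
  scrotum:
    name: scrotum
    share: 0.02
    slot_rule: fixed20
    sex_constraint: male_tech_only
    service_spec:
      kind: triangular
      min: 8.0
      mode: 14.0
      max: 23.0
  shoulder:
    name: shoulder
    share: 0.1
    slot_rule: fixed20
    sex_constraint: none
    service_spec:
      kind: triangular
      min: 9.0
      mode: 15.0
      max: 25.05
  other:
    name: other
    share: 0.27
    slot_rule: fixed20
    sex_constraint: none
    service_spec:
      kind: empirical
      values:
      - 5.0
      - 10.0
      - 15.0
      - 20.0
      - 30.0
      probs:
      - 0.0
      - 0.25
      - 0.55
      - 0.8
      - 1.0
rooms:
  id:
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  tech_sex:
  - F
  - M
  - F
  - M
  - F
  - M
priority:
  inpatient: 5
  emergency: 6
setup_spec:
  kind: triangular
  min: 1.0
  mode: 5.0
  max: 9.0
calendar:
  effective_day_minutes: 447.36
  days_per_replication: 5.0
  warmup_minutes: 5600.0
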