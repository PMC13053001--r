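schema: dermflow/arm-config/1
arm: intervention
distribution:
  A: 0.53
  B: 0.24
  C: 0.05
  D: 0.17
  E: 0.01
pathways:
  A:
    id: A
    unit_cost: 55.0
    stages:
    - kind: delay
      ref: img_wait
    - kind: service
      ref: photography
      endpoint: image_capture
    - kind: delay
      ref: review_wait
    - kind: service
      ref: remote_review
      endpoint: clinical_diagnosis
    - kind: comm
      ref: communication
      endpoint: communication
  B:
    id: B
    unit_cost: 219.0
    stages:
    - kind: delay
      ref: img_wait
    - kind: service
      ref: photography
      endpoint: image_capture
    - kind: delay
      ref: review_wait
    - kind: service
      ref: remote_review
      endpoint: clinical_diagnosis
    - kind: delay
      ref: fu_wait_B
    - kind: service
      ref: f2f_followup
    - kind: comm
      ref: communication
      endpoint: communication
  C:
    id: C
    unit_cost: 371.0
    stages:
    - kind: delay
      ref: img_wait
    - kind: service
      ref: photography
      endpoint: image_capture
    - kind: delay
      ref: review_wait
    - kind: service
      ref: remote_review
      endpoint: clinical_diagnosis
    - kind: delay
      ref: fu_wait_C
    - kind: service
      ref: f2f_followup
    - kind: delay
      ref: biopsy_wait_C
    - kind: service
      ref: biopsy
      endpoint: biopsy
    - kind: delay
      ref: histo_wait_C
      endpoint: histopath_diagnosis
    - kind: comm
      ref: communication
      endpoint: communication
  D:
    id: D
    unit_cost: 542.0
    stages:
    - kind: delay
      ref: img_wait
    - kind: service
      ref: photography
      endpoint: image_capture
    - kind: delay
      ref: review_wait
    - kind: service
      ref: remote_review
      endpoint: clinical_diagnosis
    - kind: delay
      ref: biopsy_wait_D
    - kind: service
      ref: biopsy
      endpoint: biopsy
    - kind: delay
      ref: histo_wait_D
      endpoint: histopath_diagnosis
    - kind: comm
      ref: communication
      endpoint: communication
  E:
    id: E
    unit_cost: 137.0
    stages:
    - kind: delay
      ref: img_wait
    - kind: service
      ref: photography
      endpoint: image_capture
    - kind: delay
      ref: review_wait
    - kind: service
      ref: remote_review
      endpoint: clinical_diagnosis
    - kind: delay
      ref: cancel_wait_E
    - kind: comm
      ref: communication
      endpoint: communication
delays:
  img_wait:
    mean: 4.908439814814814
    cv: 0.5
    family: lognormal
  review_wait:
    mean: 2.454219907407407
    cv: 0.5
    family: lognormal
  fu_wait_B:
    mean: 4.797583333333326
    cv: 0.5
    family: lognormal
  cancel_wait_E:
    mean: 4.807999999999993
    cv: 0.5
    family: lognormal
  fu_wait_C:
    mean: 6.6553125
    cv: 0.5
    family: lognormal
  biopsy_wait_C:
    mean: 15.529062499999998
    cv: 0.5
    family: lognormal
  histo_wait_C:
    mean: 22.184374999999999
    cv: 0.5
    family: lognormal
  biopsy_wait_D:
    mean: 17.751666666666665
    cv: 0.5
    family: lognormal
  histo_wait_D:
    mean: 26.627499999999998
    cv: 0.5
    family: lognormal
communication:
  A:
    mean: 0.62
    cv: 0.5
    mix:
      email: 0.55
      letter: 0.25
      telephone: 0.2
    rel:
      email: 0.3
      letter: 1.0
      telephone: 0.5
  B:
    mean: 0.62
    cv: 0.5
    mix:
      email: 0.55
      letter: 0.25
      telephone: 0.2
    rel:
      email: 0.3
      letter: 1.0
      telephone: 0.5
  C:
    mean: 0.62
    cv: 0.5
    mix:
      letter: 0.4
      email: 0.2
      telephone: 0.2
      f2f_appointment: 0.2
    rel:
      letter: 1.0
      email: 0.3
      telephone: 0.5
      f2f_appointment: 3.0
  D:
    mean: 0.62
    cv: 0.5
    mix:
      letter: 0.4
      email: 0.2
      telephone: 0.2
      f2f_appointment: 0.2
    rel:
      letter: 1.0
      email: 0.3
      telephone: 0.5
      f2f_appointment: 3.0
  E:
    mean: 0.62
    cv: 0.5
    mix:
      email: 0.55
      letter: 0.25
      telephone: 0.2
    rel:
      email: 0.3
      letter: 1.0
      telephone: 0.5
activities:
  photography:
    name: photography
    duration: 20.0
    role: HCA_Band3
    procedure_cost: 0.0
    license_cost: 5.0
  remote_review:
    name: remote_review
    duration: 4.97
    role: Consultant
    procedure_cost: 0.0
    license_cost: 5.0
  f2f_consult:
    name: f2f_consult
    duration: 20.0
    role: Consultant
    procedure_cost: 0.0
    license_cost: 0.0
  f2f_followup:
    name: f2f_followup
    duration: 15.0
    role: Consultant
    procedure_cost: 0.0
    license_cost: 0.0
  biopsy:
    name: biopsy
    duration: 30.0
    role: Consultant
    procedure_cost: 150.0
    license_cost: 0.0
staff:
  HCA_Band3:
    name: HCA_Band3
    hourly_rate: 29.0
    weekend_available: yes
  Band5:
    name: Band5
    hourly_rate: 43.0
    weekend_available: yes
  Band9:
    name: Band9
    hourly_rate: 104.0
    weekend_available: yes
  Consultant:
    name: Consultant
    hourly_rate: 127.0
    weekend_available: yes
  GP:
    name: GP
    hourly_rate: 90.0
    weekend_available: no
staffing:
  HCA_Band3: 2.0
  Band5: 2.0
  Band9: 1.0
  Consultant: 3.0
  GP: 2.0
arrivals:
  annual_volume: 3000.0
  monthly_weights:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
calendar:
  open_hour: 8.5
  close_hour: 18.5
  weekend_fraction: 0.7
  always_open: no
priority:
  A: 1
  B: 1
  C: 1
  D: 1
  E: 1
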