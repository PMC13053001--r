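schema: dermflow/arm-config/1
arm: comparator
distribution:
  F: 0.52
  G: 0.48
pathways:
  F:
    id: F
    unit_cost: 163.0
    stages:
    - kind: delay
      ref: consult_wait
    - kind: service
      ref: f2f_consult
      endpoint: clinical_diagnosis
    - kind: comm
      ref: communication
      endpoint: communication
  G:
    id: G
    unit_cost: 364.0
    stages:
    - kind: delay
      ref: consult_wait
    - kind: service
      ref: f2f_consult
      endpoint: clinical_diagnosis
    - kind: delay
      ref: biopsy_wait_G
    - kind: service
      ref: biopsy
      endpoint: biopsy
    - kind: delay
      ref: histo_wait_G
      endpoint: histopath_diagnosis
    - kind: comm
      ref: communication
      endpoint: communication
delays:
  consult_wait:
    mean: 17.27611111111111
    cv: 0.5
    family: lognormal
  biopsy_wait_G:
    mean: 39.164708333333337
    cv: 0.5
    family: lognormal
  histo_wait_G:
    mean: 72.73445833333335
    cv: 0.5
    family: lognormal
communication:
  F:
    mean: 2.386923076923075
    cv: 0.5
    mix:
      letter: 0.7
      telephone: 0.2
      email: 0.1
    rel:
      letter: 1.0
      telephone: 0.5
      email: 0.3
  G:
    mean: 1.889999999999986
    cv: 0.5
    mix:
      letter: 0.5
      f2f_appointment: 0.3
      telephone: 0.2
    rel:
      letter: 1.0
      f2f_appointment: 3.0
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
  F: 1
  G: 1
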