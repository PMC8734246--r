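cvd:
  clauses:
  - source: hospital
    code_prefixes:
    - I20
    - I21
    - I22
    - I25
    - I50
    - I60
    - I61
    - I63
    - I64
    min_count: 1
  - source: physician
    code_prefixes:
    - '410'
    - '411'
    - '412'
    - '413'
    - '414'
    - '428'
    - '430'
    - '431'
    - '433'
    - '434'
    - '436'
    min_count: 2
    within_days: 730
kidney_disease:
  clauses:
  - source: hospital
    code_prefixes:
    - N17
    - N18
    - N19
    min_count: 1
  - source: physician
    code_prefixes:
    - '580'
    - '581'
    - '582'
    - '583'
    - '585'
    - '586'
    min_count: 2
    within_days: 730
liver_disease:
  clauses:
  - source: hospital
    code_prefixes:
    - K70
    - K71
    - K72
    - K73
    - K74
    - K75
    - K76
    min_count: 1
  - source: physician
    code_prefixes:
    - '571'
    - '572'
    - '573'
    min_count: 2
    within_days: 730
copd:
  min_age_years: 35
  clauses:
  - source: hospital
    code_prefixes:
    - J41
    - J42
    - J43
    - J44
    min_count: 1
  - source: physician
    code_prefixes:
    - '491'
    - '492'
    - '496'
    min_count: 2
    within_days: 730
diabetes:
  clauses:
  - source: hospital
    code_prefixes:
    - E10
    - E11
    - E13
    - E14
    min_count: 1
  - source: physician
    code_prefixes:
    - '250'
    min_count: 2
    within_days: 730
  - source: pharmacy
    code_prefixes:
    - '00500100'
    - '00500101'
    - '00500102'
    - '00500103'
    min_count: 1
osteoarthritis:
  clauses:
  - source: hospital
    code_prefixes:
    - M15
    - M16
    - M17
    - M18
    - M19
    min_count: 1
  - source: physician
    code_prefixes:
    - '715'
    min_count: 2
    within_days: 730
hypertension:
  min_age_years: 20
  clauses:
  - source: hospital
    code_prefixes:
    - I10
    - I11
    - I12
    - I13
    - I15
    min_count: 1
  - source: physician
    code_prefixes:
    - '401'
    - '402'
    - '403'
    - '404'
    - '405'
    min_count: 2
    within_days: 730
alzheimers_dementia:
  min_age_years: 40
  clauses:
  - source: hospital
    code_prefixes:
    - F00
    - F01
    - F02
    - F03
    - G30
    min_count: 1
  - source: physician
    code_prefixes:
    - '290'
    - '3310'
    min_count: 2
    within_days: 730
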