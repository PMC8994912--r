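# Synthetic code lists with transparent mnemonics. Real register code lists
# (ICD-10 / NCSP) can be dropped in with the same schema: each class maps to
# patterns matched case-insensitively, dot-insensitively, by prefix.
complication_codes:
  cerebrovascular: [CER]
  cardiovascular: [CAR]
  nephropathy: [NEP]
  foot_disorder: [FOO]
  eye: [EYE]
  neurological: [NEU]
comorbidity_codes:
  myocardial_infarction: [CMMI]
  congestive_heart_failure: [CMCHF]
  peripheral_vascular_disease: [CMPVD]
  cerebrovascular_disease: [CMCVD]
  dementia: [CMDEM]
  chronic_pulmonary_disease: [CMPUL]
  rheumatological_disease: [CMRHE]
  peptic_ulcer_disease: [CMULC]
  any_chronic_liver_disease: [CMLIV]
  diabetes_with_chronic_complications: [CMDCC]
  moderate_severe_renal_disease: [CMREN]
  any_malignancy: [CMMAL]
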