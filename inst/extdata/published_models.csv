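episode_type,term,cerebrovascular,cardiovascular,nephropathy,foot_disorder,eye,neurological
incident,n,1367,1870,371,1094,855,220
incident,intercept_eur,9663.62,11143.52,7517.73,13492.7,4252.5,4785.58
incident,woman,0.85,0.83,0.98,0.90,0.93,1.25
incident,age_c75_per10,0.81,0.85,0.59,0.88,0.88,0.86
incident,t2d_duration_per5,1.05,1.02,1.06,1.02,1.02,1.00
incident,died_within_1y,1.53,1.41,1.49,1.16,2.21,2.03
incident,rheumatological_disease,1.28,1.74,1.08,1.69,2.88,1.62
incident,dementia,0.49,0.52,1.27,0.70,0.88,0.31
incident,cerebrovascular_disease,1.07,1.08,0.53,0.97,1.19,2.31
incident,congestive_heart_failure,1.36,1.55,1.47,1.30,1.29,1.26
incident,moderate_severe_renal_disease,1.33,2.25,1.03,1.75,3.21,1.95
incident,chronic_pulmonary_disease,1.00,1.07,1.09,1.28,1.18,0.98
incident,myocardial_infarction,1.39,NA,0.93,1.01,0.92,1.87
incident,any_malignancy,1.11,1.07,1.30,1.34,1.98,2.00
incident,peripheral_vascular_disease,1.36,1.36,1.69,0.89,1.97,1.67
incident,peptic_ulcer_disease,1.45,1.06,1.07,1.02,1.68,0.16
incident,any_chronic_liver_disease,1.27,1.22,1.08,1.35,1.15,1.96
incident,mcfadden_r2,0.107,0.090,0.156,0.065,0.165,0.248
recurrent,n,855,5355,625,1172,2228,136
recurrent,intercept_eur,8980.94,7865.37,4723.3,12005.25,3208.07,5997.52
recurrent,woman,0.91,0.90,1.20,0.96,1.10,0.87
recurrent,age_c75_per10,0.86,0.83,0.77,0.82,0.94,0.89
recurrent,t2d_duration_per5,1.00,1.01,1.07,1.03,1.00,1.00
recurrent,died_within_1y,1.05,1.28,1.20,1.40,1.87,2.12
recurrent,n_earlier_episodes,0.97,1.00,1.03,1.05,1.04,0.87
recurrent,high_prior_cost,1.62,2.19,2.39,1.75,3.57,4.61
recurrent,rheumatological_disease,1.77,1.73,1.11,1.33,1.54,9.87
recurrent,dementia,0.84,0.87,0.36,0.69,0.72,1.56
recurrent,cerebrovascular_disease,0.80,1.06,0.89,0.85,1.38,1.06
recurrent,congestive_heart_failure,0.98,0.98,1.10,0.88,1.15,0.91
recurrent,diabetes_with_chronic_complications,1.50,1.32,1.68,1.24,0.94,1.70
recurrent,moderate_severe_renal_disease,1.66,1.49,1.55,2.00,3.20,0.97
recurrent,chronic_pulmonary_disease,1.29,1.23,1.25,1.17,1.09,0.78
recurrent,myocardial_infarction,1.00,1.11,1.32,1.26,1.51,1.30
recurrent,any_malignancy,1.03,1.37,1.12,0.93,1.56,2.21
recurrent,peripheral_vascular_disease,1.29,1.26,1.28,0.78,1.73,1.42
recurrent,peptic_ulcer_disease,1.36,1.43,2.19,1.04,1.25,0.24
recurrent,any_chronic_liver_disease,2.03,1.48,1.35,1.01,1.18,3.46
recurrent,mcfadden_r2,0.094,0.115,0.267,0.146,0.230,0.327
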