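quantity,value
episodes_cardiovascular,7225
episodes_eye,3083
episodes_foot_disorder,2266
episodes_cerebrovascular,2222
episodes_nephropathy,996
episodes_neurological,356
episodes_included_total,16148
patients_with_episodes,7895
person_years,102803
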