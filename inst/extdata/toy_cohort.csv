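patient_id,age,sex,mechanism,hr,sbp,dbp,fast,lactate,gcs,iss,abdominal_ais,pelvic_ais,rts,triss,sofa,fibrinogen,transfused,blood_units,mtp,laparotomy,management,icu_los,hospital_los,mortality
T-001,34,male,blunt,72,128,76,negative,1.2,15,9,2,,7.84,0.99,1,3.1,FALSE,0,FALSE,FALSE,conservative,1,4,FALSE
T-002,51,female,blunt,104,96,58,positive,3.4,14,22,3,2,7.55,0.95,3,2.2,TRUE,4,FALSE,TRUE,surgical,4,12,FALSE
T-003,27,male,penetrating,128,84,50,positive,5.1,12,34,4,,6.10,0.70,6,1.5,TRUE,12,TRUE,TRUE,surgical_plus_ir,9,21,FALSE
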