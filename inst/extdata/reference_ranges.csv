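analyte,sex,low,high,unit
crp,both,0,0.3,mg/dL
hemoglobin,male,13.5,17.5,g/dL
hemoglobin,female,11.5,15,g/dL
platelets,both,14,34,10^4/uL
leukocytes,both,3300,9000,/uL
blood_sugar,both,70,109,mg/dL
ast,both,10,40,IU/L
alt,both,5,45,IU/L
creatinine,male,0.61,1.04,mg/dL
creatinine,female,0.47,0.79,mg/dL
bun,both,8,20,mg/dL
uric_acid,male,3.8,7,mg/dL
uric_acid,female,2.5,7,mg/dL
sodium,both,137,147,mEq/L
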