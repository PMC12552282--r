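patient_id,weight_kg,kv,ctdi_vol_mgy,scan_length_cm,protocol_label
p01,58,80,4.1,25,WA
p02,66,80,5.2,25,WA
p03,73,100,7.9,25,WA
p04,78,100,8.4,25,WA
p05,91,120,11.6,25,WA
p06,64,120,9.8,25,SD
p07,76,120,10.4,25,SD
p08,88,120,10.3,25,SD
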