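muscle,volume_mean_cm3,volume_sd_cm3,length_mean_cm,length_sd_cm
ABDH,20.88,4.36,12.82,0.97
ABDM,15.47,2.92,11.31,1.04
ADDH_OH,12.97,2.16,6.34,0.54
ADDH_TH,1.34,0.52,2.80,0.39
FDB,16.66,3.33,10.78,1.05
FHB,12.74,2.35,7.39,1.25
QP,11.01,2.62,9.20,0.72
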