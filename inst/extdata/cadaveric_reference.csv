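muscle,head,fl_to_length_ratio,cadaveric_fl_cm,pennation_deg,source
ABDH,all,0.20,2.30,16.50,Kura 1997; Ledoux 2001
ABDM,all,0.25,2.39,19.10,Kura 1997; Ledoux 2001
ADDH_OH,all,0.29,1.86,9.00,Kura 1997; Ledoux 2001
ADDH_TH,all,0.82,1.87,13.30,Kura 1997; Ledoux 2001
FDB,all,0.25,2.18,11.40,Kura 1997; Ledoux 2001
FDB,toe2,0.28,2.54,15.40,Kura 1997; Ledoux 2001
FDB,toe3,0.24,2.28,11.70,Kura 1997; Ledoux 2001
FDB,toe4,0.22,2.08,7.00,Kura 1997; Ledoux 2001
FDB,toe5,NA,1.82,NA,Kura 1997
FHB,all,0.28,1.70,7.80,Kura 1997; Ledoux 2001
FHB,medial,0.29,1.75,NA,Kura 1997
FHB,lateral,0.26,1.65,NA,Kura 1997
QP,all,0.47,2.55,8.10,Kura 1997; Ledoux 2001
QP,medial,0.50,2.75,NA,Kura 1997
QP,lateral,0.44,2.34,NA,Kura 1997
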