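patient_id,pib_positive,pathology,criteria,fdg_visual,fdg_quant,mri
2,0,CBD,FV,TPV,TPV,FV
3,0,CBD,FV,FV,FV,FV
8,0,CBD,TPV,TPV,TPV,NA
10,0,PSP,FV,FV,FV,TPV
14,0,Pick's disease + LBD,TPV,FV,FV,FV
13,1,AD + CBD,TPV,TPV,TPV,TPV
18,1,AD + LBD,TPV,TPV,TPV,TPV
19,1,AD + LBD,TPV,TPV,TPV,FV
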