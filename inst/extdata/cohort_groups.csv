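label,location,kind,n,age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd,sbp_mean,sbp_sd,dbp_mean,dbp_sd,hct_mean,hct_sd,protein_mean,protein_sd,female_freq,right_arm_freq,hypertension_freq,diabetes_freq
RC S-E,radio-cephalic,end-to-side,32,60,16,168,11,75,18,136,17,76,9,33,5,6.5,0.7,0.41,0.25,0.78,0.18
RC E-E,radio-cephalic,end-to-end,13,62,15,170,9,75,12,145,19,82,14,34,3,6.8,0.6,0.00,0.08,0.85,0.08
RC S-S,radio-cephalic,side-to-side,5,67,15,168,3,72,8,124,18,74,17,34,5,6.5,0.5,0.00,0.20,1.00,0.00
BC S-E,brachio-cephalic,end-to-side,7,57,14,166,7,61,9,139,13,80,6,36,4,6.8,0.7,0.86,0.14,1.00,0.00
BC S-S,brachio-cephalic,side-to-side,3,72,11,158,3,68,11,133,15,83,6,39,1,6.3,0.4,1.00,0.33,1.00,0.33
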