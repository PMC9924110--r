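device,tps_spr,tps_spr_sd,measured_spr,measured_spr_sd,spr_pct_diff,spr_pct_diff_sd,wet_diff_mm,wet_diff_sd_mm
QFix MOLDCARE cushion,0.080,0.006,0.101,0.009,-20.9,4.6,-0.9,0.4
CIVCO Vac-Lok bag,0.052,0.003,0.070,0.002,-26.0,2.9,-1.3,0.4
Exafast Dental Putty,1.519,0.031,1.517,0.051,0.2,5.4,0.0,0.5
Thin sheets (16 layers),0.171,0.002,0.200,0.003,-14.4,0.4,-0.2,0.0
Thick sheets (16 layers),0.129,0.011,0.150,0.011,-14.0,1.8,-0.5,0.1
Sage Bite Block (foam),0.212,NA,0.241,NA,-12.1,NA,-0.4,NA
Sage Bite Block (handle),0.364,NA,0.485,NA,-24.9,NA,-0.3,NA
kVue BoS Insert (head),0.790,NA,1.100,NA,-28.2,NA,-0.9,NA
kVue BoS Insert (body),0.122,NA,0.189,NA,-35.1,NA,-2.2,NA
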