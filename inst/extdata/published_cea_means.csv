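intervention_id,cost,qaly
nrt_low,10259,10.934
ecig_low,10279,11.290
bupropion_low,10283,11.038
nrt_std,10292,11.119
bupropion_std,10304,11.033
nrt_high,10309,11.092
ecig_high,10319,11.189
bupropion_std_nrt_high,10346,11.128
varenicline_std,10413,11.127
varenicline_std_bupropion_std,10437,11.281
varenicline_low,10440,10.959
varenicline_std_nrt_high,10467,11.117
varenicline_low_nrt_std,10587,11.273
varenicline_std_nrt_std,10587,11.280
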