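site,pretreatment_days,tb_mean_c,tb_sd_c,theta50_cd
IS,60,3.34,1.03,115
IS,90,-1.96,1.23,130
TM,60,2.15,0.86,112
TM,90,-1.58,3.74,108
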