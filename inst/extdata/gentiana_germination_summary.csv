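site,pretreatment_days,temperature_c,mean_pct,sd_pct
IS,0,5,2.00,4.00
IS,0,10,0.00,0.00
IS,0,15,0.00,0.00
IS,0,20,2.27,4.55
IS,0,25,2.22,2.57
IS,0,30,0.00,0.00
IS,15,5,17.21,6.16
IS,15,10,1.00,2.00
IS,15,15,0.00,0.00
IS,15,20,1.00,2.00
IS,15,25,0.00,0.00
IS,15,30,1.19,2.38
IS,30,5,26.20,8.75
IS,30,10,15.62,9.01
IS,30,15,34.63,8.74
IS,30,20,31.71,14.24
IS,30,25,10.20,4.34
IS,30,30,0.00,0.00
IS,60,5,27.01,6.60
IS,60,10,55.70,17.52
IS,60,15,65.08,5.32
IS,60,20,58.25,6.52
IS,60,25,29.17,6.18
IS,60,30,2.27,4.55
IS,90,5,82.67,1.81
IS,90,10,90.00,4.00
IS,90,15,92.83,7.13
IS,90,20,93.96,3.97
IS,90,25,15.00,3.83
IS,90,30,2.27,4.55
TM,0,5,1.14,2.27
TM,0,10,0.00,0.00
TM,0,15,0.00,0.00
TM,0,20,0.00,0.00
TM,0,25,0.00,0.00
TM,0,30,1.09,2.17
TM,15,5,8.46,7.06
TM,15,10,0.00,0.00
TM,15,15,0.00,0.00
TM,15,20,0.00,0.00
TM,15,25,1.19,2.38
TM,15,30,0.00,0.00
TM,30,5,29.67,10.75
TM,30,10,26.47,11.77
TM,30,15,34.21,3.29
TM,30,20,22.86,6.75
TM,30,25,1.25,2.50
TM,30,30,0.00,0.00
TM,60,5,28.01,17.79
TM,60,10,46.20,12.25
TM,60,15,60.33,11.13
TM,60,20,38.20,14.10
TM,60,25,3.31,4.18
TM,60,30,0.00,0.00
TM,90,5,82.67,1.81
TM,90,10,90.00,4.00
TM,90,15,92.83,7.13
TM,90,20,93.96,3.97
TM,90,25,15.00,3.83
TM,90,30,0.00,0.00
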