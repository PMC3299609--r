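component,mean_units,sd_units,total_units,cost_mean,cost_sd,total_cost
gp,1.71,1.42,77,184,153,8266
pt,8.20,13.62,369,409,680,18415
xray,0.33,NA,15,22,31,979
ultrasound,0.27,NA,12,33,56,1490
medicine,0.47,NA,21,6,7,262
healthcare_total,NA,NA,NA,654,671,29412
sick_leave,40.82,50.98,1837,7875,9833,354356
total,NA,NA,NA,8528,9829,383768
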