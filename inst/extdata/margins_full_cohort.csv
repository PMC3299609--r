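component,mean_units,sd_units,total_units,cost_mean,cost_sd,total_cost
gp,0.89,0.97,181,95,105,19429
pt,3.91,7.40,798,195,369,39825
xray,0.28,0.45,57,18,29,3719
ultrasound,0.11,0.31,23,14,39,2857
medicine,0.28,NA,58,4,6,718
healthcare_total,NA,NA,NA,326,389,66548
sick_leave,9.04,29.17,1844,1743,5626,355610
total,NA,NA,NA,2069,5730,422158
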