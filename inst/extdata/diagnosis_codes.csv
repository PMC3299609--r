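category,code
subacromial_pain,M751-9
subacromial_pain,M759P
subacromial_pain,M709
subacromial_pain,M779
subacromial_pain,M791
subacromial_pain,M799
subacromial_pain,M255
subacromial_pain,M255B
subacromial_pain,M629
subacromial_pain,M795
subacromial_pain,M796B
stiffness,M750
stiffness,M190B
stiffness,M192B
fracture,S420
fracture,S4200
fracture,S429
dislocation,S430
dislocation,S431
dislocation,S435
dislocation,S460
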