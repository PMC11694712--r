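cohort,stratum,group,feasible,total
AR,overall,overall,25,45
MR,overall,overall,20,45
AR,severity,mild,14,19
AR,severity,moderate,9,18
AR,severity,severe,2,8
MR,severity,mild,17,30
MR,severity,moderate,2,11
MR,severity,severe,1,4
AR,jet_direction,central,20,28
AR,jet_direction,eccentric,5,17
MR,jet_direction,central,16,27
MR,jet_direction,eccentric,4,18
AR,image_quality,moderate_or_better,23,37
AR,image_quality,below_moderate,2,8
MR,image_quality,moderate_or_better,18,34
MR,image_quality,below_moderate,2,11
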