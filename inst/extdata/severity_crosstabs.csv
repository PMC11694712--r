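cohort,tte_grade,rvol_lt30,rvol_30_59,rvol_ge60
AR,mild,19,0,0
AR,moderate,9,5,2
AR,severe,0,0,8
MR,mild,17,0,0
MR,moderate,1,4,0
MR,severe,0,0,2
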