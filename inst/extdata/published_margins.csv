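factor,level,n,n_pos
overall,all,993,208
age,21-30,2,0
age,31-40,61,14
age,41-50,258,73
age,51-60,292,62
age,61-70,239,39
age,71-80,126,18
age,81-90,14,2
age,>90,1,0
diameter,T1,748,130
diameter,T2,231,69
diameter,T3,14,9
histology,ductal,718,129
histology,lobular,64,17
histology,unknown,211,62
er,pos,872,192
er,neg,121,16
pr,pos,759,169
pr,neg,234,39
ki67,neg,664,132
ki67,pos,329,76
her2,neg,870,180
her2,pos,117,26
her2,unknown,6,2
grading,G1,106,32
grading,G2,176,47
grading,G3,115,30
grading,unknown,596,99
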