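stratum,type,observed
50-54,age,1.6
55-59,age,1.1
60-64,age,1.0
65-69,age,1.5
70-74,age,1.9
1,grade,0.2
2,grade,0.5
3,grade,0.6
total,total,1.38
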