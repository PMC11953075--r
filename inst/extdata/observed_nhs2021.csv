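stratum,type,observed
50-54,age,1.6
55-59,age,1.5
60-64,age,1.8
65-69,age,1.9
70-74,age,2.4
total,total,1.7
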