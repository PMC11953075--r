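parameter,low,high
onset,0.9,1.1
progression,0.9,1.1
mortality,0.9,1.1
regression,0.0439,0.0537
clinical,0.045,0.055
sensitivity,0.774,0.946
participation,0.684,0.836
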