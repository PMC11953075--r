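lower,upper,first,last
0,0,0.350,0.350
1,9,0.020,0.008
10,19,0.008,0.020
20,29,0.022,0.030
30,39,0.035,0.075
40,49,0.090,0.230
50,59,0.260,0.520
60,69,0.600,1.300
70,79,1.400,3.800
80,89,4.500,13.50
90,99,15.50,33.00
100,100,100.0,100.0
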