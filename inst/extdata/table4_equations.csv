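trait,term,coefficient
Y1,(Intercept),-471.633
Y1,C2,36.999
Y1,S3,0.637
Y1,S5,-3.499
Y1,S6,0.184
Y1,S10,0.93
Y1,S12,9.681
Y2,(Intercept),79.618
Y2,S3,-0.136
Y2,S4,-0.014
Y2,S5,-0.84
Y2,S6,0.018
Y2,S8,0.003
Y2,S11,0.008
Y2,S12,1.222
Y3,(Intercept),0.126
Y3,C2,4.154
Y3,S3,0.115
Y3,S4,0.002
Y3,S5,0.341
Y3,S6,0.023
Y4,(Intercept),1.278
Y4,C2,-0.016
Y4,T1,-0.00002
Y4,T2,0.001
Y4,S5,-0.011
Y4,S6,-0.0001
Y5,(Intercept),7.421
Y5,C1,0.004
Y5,C2,2.596
Y5,T1,0.013
Y5,T2,0.058
Y5,S7,-0.205
Y6,(Intercept),69.033
Y6,C1,-0.03
Y6,S3,-0.104
Y6,S9,-5.659
Y6,S12,1.777
Y7,(Intercept),51.316
Y7,C1,-0.003
Y7,T1,0.01
Y7,T2,0.061
Y7,S7,-0.283
Y7,S10,0.129
Y8,(Intercept),-0.901
Y8,C1,0.001
Y8,C2,0.01
Y8,T1,0.0004
Y8,S3,0.001
Y8,S9,0.098
Y9,(Intercept),1.577
Y9,S1,-0.112
Y9,S9,0.612
Y9,S11,0.001
Y9,S12,-0.133
Y10,(Intercept),53.934
Y10,C1,-0.032
Y10,T1,0.003
Y10,S1,2.009
Y10,S5,2.123
Y10,S7,0.234
Y10,S11,-0.418
Y10,S12,0.725
Y11,(Intercept),38.014
Y11,T1,-0.016
Y11,S5,6.711
Y11,S6,-0.02
Y11,S7,0.071
Y11,S8,0.004
Y11,S9,3.977
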