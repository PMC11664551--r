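trait,F,p
Y1,4.35,0.001
Y2,2.78,0.012
Y3,5.11,<0.001
Y4,2.34,0.047
Y5,8.09,<0.001
Y6,4.34,0.003
Y7,4.06,0.002
Y8,4.49,0.001
Y9,6.29,<0.001
Y10,4.45,<0.001
Y11,4.39,<0.001
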