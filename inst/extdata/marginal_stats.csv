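code,mean,std,min,max
C1,1752.61,56.63,1634.80,1855.20
C2,20.23,0.38,18.93,20.93
T1,275.61,85.97,161.00,524.00
T2,9.64,5.95,0.34,29.11
S1,4.84,0.75,3.70,7.50
S2,4.72,1.46,1.96,11.64
S3,21.33,8.05,6.88,44.64
S4,78.60,29.25,28.60,155.00
S5,0.72,0.51,0.14,3.49
S6,65.72,54.44,0.37,231.25
S7,6.98,2.26,3.11,14.12
S8,245.41,98.78,59.00,497.00
S9,0.46,0.21,0.08,0.88
S10,3.39,4.98,0.36,41.30
S11,2.66,2.94,0.01,16.30
S12,0.65,0.61,0.10,4.00
Y1,308.95,48.20,214.39,518.19
Y2,83.56,4.05,74.30,100.05
Y3,88.51,5.69,74.78,102.74
Y4,0.95,0.03,0.86,1.04
Y5,68.91,2.33,60.20,73.37
Y6,12.91,6.97,-6.19,23.04
Y7,47.45,3.40,38.49,54.62
Y8,1.31,0.14,1.11,1.72
Y9,1.23,0.42,0.41,2.14
Y10,10.02,4.53,5.04,27.65
Y11,40.54,7.92,25.51,61.29
TSS,10.66,0.93,8.73,13.17
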