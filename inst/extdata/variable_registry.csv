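code,name,unit,category,sense
C1,annual average precipitation,mm,meteorological,none
C2,annual average temperature,degC,meteorological,none
T1,elevation,m,topographic,none
T2,slope,deg,topographic,none
S1,pH,dimensionless,soil,none
S2,clay,%,soil,none
S3,soil organic matter,g/kg,soil,none
S4,hydrolyzed N,mg/kg,soil,none
S5,total P,g/kg,soil,none
S6,Olsen P,mg/kg,soil,none
S7,cation exchange capacity,cmol/kg,soil,none
S8,available K,mg/kg,soil,none
S9,available B,mg/kg,soil,none
S10,available Zn,mg/kg,soil,none
S11,exchangeable Ca,cmol/kg,soil,none
S12,exchangeable Mg,cmol/kg,soil,none
Y1,fruit weight,g,quality,maximize
Y2,horizontal diameter,mm,quality,maximize
Y3,vertical diameter,mm,quality,maximize
Y4,shape index,dimensionless,quality,minimize
Y5,peel luminance L*,dimensionless,quality,maximize
Y6,peel green-red difference a*,dimensionless,quality,maximize
Y7,peel yellow-blue difference b*,dimensionless,quality,maximize
Y8,peel hue angle H,dimensionless,quality,maximize
Y9,titratable acid,%,quality,minimize
Y10,solid-acid ratio TSS/TA,dimensionless,quality,maximize
Y11,vitamin C,%,quality,maximize
TSS,total soluble solids,%,quality,none
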