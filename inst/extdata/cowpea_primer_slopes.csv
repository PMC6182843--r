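category,gene,slope_magnitude,efficiency_pct,r_squared_printed,y_intercept
CRG,VuACT,3.18,106.28,0.989,35.09
CRG,bTUB,3.25,103.09,0.993,35.34
CRG,EF1a,3.38,97.63,0.995,33.12
CRG,FBOX,3.28,101.78,0.982,35.77
CRG,UE21D,3.30,100.92,0.995,34.63
CRG,VuUBQ10,3.40,96.84,0.997,38.01
CRG,UNK,3.35,98.84,0.989,35.17
TT,VuChiB,3.40,96.84,0.996,38.03
TT,VuLTP,3.38,97.24,0.995,35.56
TT,VuCHI,3.43,95.68,0.996,37.01
TT,VuCHS,3.31,100.50,0.996,33.69
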