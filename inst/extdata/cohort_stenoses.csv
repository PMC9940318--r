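patient,location,length_cm,pct_diameter,ifr,ffr
1,LAD,2.2,90,0.73,0.68
1,CIRC,0.7,95,0.50,0.52
1,RCA,0.6,99,0.29,0.38
2,LAD,0.9,95,0.85,0.76
2,OM1,2,75,0.86,0.77
2,RCA,1.8,99,0.23,0.34
3,LAD1,0.5,40,0.99,0.85
3,LAD2,1.1,85,0.84,0.75
3,CIRC1,0.4,30,1.00,0.86
3,CIRC2,0.8,75,0.82,0.74
3,RCA1,0.9,45,0.98,0.85
3,RCA2,2,90,0.53,0.54
4,LMCA,1.2,80,0.89,0.79
4,LAD,0.8,75,0.94,0.82
4,RCA,1.5,95,0.56,0.56
4,PLB,1,30,0.95,0.83
5,LAD,1.6,90,0.93,0.81
5,OM2,1.2,99,0.29,0.38
5,RCA,1.5,90,0.73,0.68
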