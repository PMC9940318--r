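patient,region,diseased_ml_min,healthy_ml_min
1,LAD,99.17,106.48
1,CIRC,25.43,75.76
1,RCA,28.68,91.74
2,LAD,101.12,116.91
2,CIRC,56.76,60.97
2,RCA,21.05,74.36
3,LAD,80.83,90.49
3,CIRC,69.64,83.57
3,RCA,55.52,70.50
4,LAD,79.88,94.54
4,CIRC,61.31,71.72
4,RCA,51.84,81.55
5,LAD,87.48,95.95
5,CIRC,33.27,61.69
5,RCA,57.83,71.40
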