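patient,config,region,graft,target_site,mgf_ml_min,pi,perfusion_ml_min
1,A,LAD,LIMA to LAD,LAD,17.57,1.54,105.92
1,A,CIRC,RIMA to OM1,OM,45.01,1.61,61.88
1,A,RCA,RIMA to PDA,PDA,61.91,1.24,84.56
1,B,LAD,LIMA to LAD,LAD,21.47,1.30,107.39
1,B,CIRC,RIMA to OM1,OM,44.99,1.52,61.84
1,B,RCA,Radial to PDA,PDA,64.99,1.46,87.33
1,C,LAD,LIMA to LAD,LAD,21.47,1.30,107.40
1,C,CIRC,Radial to OM1,OM,56.08,1.24,70.75
1,C,RCA,RIMA to PDA,PDA,55.01,1.20,78.40
1,D,LAD,RIMA to LAD,LAD,20.59,1.43,107.07
1,D,CIRC,LIMA to OM1,OM,45.86,1.56,62.56
1,D,RCA,Radial to PDA,PDA,64.99,1.46,87.33
1,E,LAD,LIMA to LAD,LAD,17.20,1.65,105.77
1,E,CIRC,Radial to OM1,OM,49.39,1.61,65.37
1,E,RCA,RIMA to PDA,PDA,55.01,1.20,78.40
1,F,LAD,LIMA to LAD,LAD,21.47,1.31,107.39
1,F,CIRC,RIMA to OM1,OM,40.09,1.65,57.91
1,F,RCA,Radial to PDA,PDA,58.47,1.43,81.50
1,G,LAD,LIMA to LAD,LAD,13.75,1.65,104.47
1,G,CIRC,RIMA to OM1,OM,37.75,1.84,56.04
1,G,RCA,Radial to PDA,PDA,51.68,1.44,75.32
1,H,LAD,LIMA to LAD,LAD,14.66,1.61,104.81
1,H,CIRC,RIMA to OM1,OM,78.94,0.91,54.91
1,H,RCA,RIMA to PDA,PDA,42.65,1.15,67.23
1,I,LAD,LIMA to LAD,LAD,21.47,1.31,107.39
1,I,CIRC,Radial to OM1,OM,29.56,2.28,49.46
1,I,RCA,RIMA to PDA,PDA,77.33,1.05,71.88
1,J,LAD,LIMA to LAD,LAD,21.47,1.31,107.39
1,J,CIRC,RIMA to OM1,OM,77.04,0.96,51.70
1,J,RCA,Radial to PDA,PDA,44.74,1.10,69.11
1,K,LAD,RIMA to LAD,LAD,54.75,1.95,102.49
1,K,CIRC,LIMA to OM1,OM,40.91,1.75,58.57
1,K,RCA,Radial to PDA,PDA,46.23,1.48,70.48
1,L,LAD,LIMA to LAD,LAD,51.13,1.10,102.43
1,L,CIRC,RIMA to OM1,OM,44.99,1.52,61.84
1,L,RCA,Radial to PDA,PDA,38.51,1.05,63.50
2,A,LAD,LIMA to LAD,LAD,37.92,1.33,115.87
2,A,CIRC,RIMA to OM1,OM,14.20,4.90,60.18
2,A,RCA,RIMA to PDA,PDA,49.37,0.76,67.90
2,B,LAD,LIMA to LAD,LAD,40.61,1.48,116.92
2,B,CIRC,RIMA to OM1,OM,19.57,3.58,61.39
2,B,RCA,Radial to PDA,PDA,51.12,0.85,69.57
2,C,LAD,LIMA to LAD,LAD,40.57,1.49,116.95
2,C,CIRC,Radial to OM1,OM,27.92,2.73,63.32
2,C,RCA,RIMA to PDA,PDA,45.11,0.92,63.87
2,D,LAD,RIMA to LAD,LAD,36.81,1.61,115.50
2,D,CIRC,LIMA to OM1,OM,20.02,3.68,61.51
2,D,RCA,Radial to PDA,PDA,51.12,0.85,69.57
2,E,LAD,LIMA to LAD,LAD,37.45,1.34,115.70
2,E,CIRC,Radial to OM1,OM,16.54,4.92,60.69
2,E,RCA,RIMA to PDA,PDA,45.11,0.92,63.87
2,F,LAD,LIMA to LAD,LAD,40.63,1.49,116.89
2,F,CIRC,RIMA to OM1,OM,13.67,5.20,60.05
2,F,RCA,Radial to PDA,PDA,48.41,0.94,67.01
2,G,LAD,LIMA to LAD,LAD,31.14,1.64,113.26
2,G,CIRC,RIMA to OM1,OM,4.52,16.44,57.93
2,G,RCA,Radial to PDA,PDA,44.38,0.84,63.17
2,H,LAD,LIMA to LAD,LAD,32.68,1.56,113.83
2,H,CIRC,RIMA to OM1,OM,41.15,1.47,57.25
2,H,RCA,RIMA to PDA,PDA,39.62,0.68,58.66
2,I,LAD,LIMA to LAD,LAD,40.68,1.48,116.83
2,I,CIRC,Radial to OM1,OM,0.68,114.35,57.06
2,I,RCA,RIMA to PDA,PDA,45.60,1.21,63.71
2,J,LAD,LIMA to LAD,LAD,40.68,1.48,116.84
2,J,CIRC,RIMA to OM1,OM,44.59,1.31,57.27
2,J,RCA,Radial to PDA,PDA,43.04,0.63,61.91
2,K,LAD,RIMA to LAD,LAD,58.93,1.41,109.01
2,K,CIRC,LIMA to OM1,OM,10.71,6.86,59.32
2,K,RCA,Radial to PDA,PDA,39.02,0.93,58.10
2,L,LAD,LIMA to LAD,LAD,54.69,1.05,109.82
2,L,CIRC,RIMA to OM1,OM,19.59,3.57,61.37
2,L,RCA,Radial to PDA,PDA,27.02,0.87,46.70
3,A,LAD,LIMA to LAD,LAD,26.73,1.41,91.18
3,A,CIRC,RIMA to OM1,OM,34.10,2.05,85.51
3,A,RCA,RIMA to PDA,PDA,28.57,1.02,75.99
3,B,LAD,LIMA to LAD,LAD,31.25,1.43,92.88
3,B,CIRC,RIMA to OM1,OM,36.19,1.89,86.48
3,B,RCA,Radial to PDA,PDA,29.32,1.24,76.53
3,C,LAD,LIMA to LAD,LAD,31.18,1.43,92.95
3,C,CIRC,Radial to OM1,OM,50.41,1.39,92.86
3,C,RCA,RIMA to PDA,PDA,26.72,1.34,74.69
3,D,LAD,RIMA to LAD,LAD,29.24,1.53,92.15
3,D,CIRC,LIMA to OM1,OM,37.17,1.93,86.93
3,D,RCA,Radial to PDA,PDA,29.32,1.24,76.53
3,E,LAD,LIMA to LAD,LAD,26.03,1.48,90.95
3,E,CIRC,Radial to OM1,OM,39.23,2.05,87.80
3,E,RCA,RIMA to PDA,PDA,26.72,1.34,74.69
3,F,LAD,LIMA to LAD,LAD,31.26,1.43,92.86
3,F,CIRC,RIMA to OM1,OM,32.99,2.11,85.04
3,F,RCA,Radial to PDA,PDA,27.05,1.35,74.92
3,G,LAD,LIMA to LAD,LAD,24.17,1.56,90.20
3,G,CIRC,RIMA to OM1,OM,29.76,2.44,83.54
3,G,RCA,Radial to PDA,PDA,23.94,1.40,72.71
3,H,LAD,LIMA to LAD,LAD,24.75,1.52,90.40
3,H,CIRC,RIMA to OM1,OM,49.44,1.29,82.86
3,H,RCA,RIMA to PDA,PDA,21.22,1.32,70.78
3,I,LAD,LIMA to LAD,LAD,31.30,1.43,92.82
3,I,CIRC,Radial to OM1,OM,24.68,2.89,81.28
3,I,RCA,RIMA to PDA,PDA,47.96,1.11,72.28
3,J,LAD,LIMA to LAD,LAD,31.25,1.43,92.88
3,J,CIRC,RIMA to OM1,OM,36.19,1.90,86.48
3,J,RCA,Radial to PDA,PDA,29.87,1.03,76.93
3,K,LAD,RIMA to LAD,LAD,41.47,2.06,88.56
3,K,CIRC,LIMA to OM1,OM,31.87,2.26,84.45
3,K,RCA,Radial to PDA,PDA,21.78,1.68,71.18
3,L,LAD,LIMA to LAD,LAD,36.45,1.23,89.35
3,L,CIRC,RIMA to OM1,OM,36.20,1.89,86.47
3,L,RCA,Radial to PDA,PDA,9.92,3.03,62.69
4,A,LAD,LIMA to LAD,LAD,38.82,0.99,98.88
4,A,CIRC,RIMA to OM2,OM,30.07,2.75,74.26
4,A,RCA,RIMA to PDA,PDA,46.88,0.83,78.67
4,B,LAD,LIMA to LAD,LAD,42.99,1.07,100.95
4,B,CIRC,RIMA to OM2,OM,34.49,2.32,76.03
4,B,RCA,Radial to PDA,PDA,49.71,1.04,80.24
4,C,LAD,LIMA to LAD,LAD,42.51,1.08,101.54
4,C,CIRC,Radial to OM2,OM,49.54,1.77,81.47
4,C,RCA,RIMA to PDA,PDA,40.79,1.26,75.23
4,D,LAD,RIMA to LAD,LAD,39.95,1.15,99.69
4,D,CIRC,LIMA to OM2,OM,35.61,2.37,76.31
4,D,RCA,Radial to PDA,PDA,49.71,1.04,80.24
4,E,LAD,LIMA to LAD,LAD,37.93,1.03,98.75
4,E,CIRC,Radial to OM2,OM,35.10,2.78,76.04
4,E,RCA,RIMA to PDA,PDA,40.79,1.26,75.23
4,F,LAD,LIMA to LAD,LAD,43.17,1.07,100.73
4,F,CIRC,RIMA to OM2,OM,28.88,2.78,74.02
4,F,RCA,Radial to PDA,PDA,43.91,1.31,76.99
4,G,LAD,LIMA to LAD,LAD,35.07,1.07,96.82
4,G,CIRC,RIMA to OM2,OM,22.40,3.87,71.32
4,G,RCA,Radial to PDA,PDA,35.80,1.28,72.42
4,H,LAD,LIMA to LAD,LAD,36.31,1.04,97.28
4,H,CIRC,RIMA to OM2,OM,49.84,1.46,70.84
4,H,RCA,RIMA to PDA,PDA,28.95,1.04,68.53
4,I,LAD,LIMA to LAD,LAD,43.54,1.06,100.27
4,I,CIRC,Radial to OM2,OM,17.34,4.94,69.87
4,I,RCA,RIMA to PDA,PDA,53.14,1.12,72.43
4,J,LAD,LIMA to LAD,LAD,43.45,1.06,100.39
4,J,CIRC,RIMA to OM2,OM,53.22,1.23,70.93
4,J,RCA,Radial to PDA,PDA,33.00,0.99,70.83
4,K,LAD,RIMA to LAD,LAD,57.17,1.55,94.37
4,K,CIRC,LIMA to OM2,OM,27.34,3.14,72.82
4,K,RCA,Radial to PDA,PDA,28.33,1.69,68.18
4,L,LAD,LIMA to LAD,LAD,48.58,1.03,97.29
4,L,CIRC,RIMA to OM2,OM,34.58,2.32,75.96
4,L,RCA,Radial to PDA,PDA,10.53,2.61,57.97
5,A,LAD,LIMA to LAD,LAD,10.77,7.11,88.99
5,A,CIRC,RIMA to OM2,OM,43.34,1.67,76.51
5,A,RCA,RIMA to PDA,PDA,34.16,1.82,70.98
5,B,LAD,LIMA to LAD,LAD,24.47,2.98,90.80
5,B,CIRC,RIMA to OM2,OM,42.79,1.68,75.95
5,B,RCA,Radial to PDA,PDA,36.60,2.03,71.88
5,C,LAD,LIMA to LAD,LAD,24.47,2.98,90.80
5,C,CIRC,Radial to OM2,OM,50.40,1.50,83.53
5,C,RCA,RIMA to PDA,PDA,29.02,2.07,69.07
5,D,LAD,RIMA to LAD,LAD,21.09,3.21,90.37
5,D,CIRC,LIMA to OM2,OM,43.41,1.74,76.60
5,D,RCA,Radial to PDA,PDA,36.60,2.03,71.88
5,E,LAD,LIMA to LAD,LAD,9.78,8.40,88.85
5,E,CIRC,Radial to OM2,OM,46.51,1.69,79.64
5,E,RCA,RIMA to PDA,PDA,29.02,2.08,69.06
5,F,LAD,LIMA to LAD,LAD,24.47,2.98,90.80
5,F,CIRC,RIMA to OM2,OM,40.95,1.75,74.10
5,F,RCA,Radial to PDA,PDA,29.37,2.46,69.18
5,G,LAD,LIMA to LAD,LAD,4.11,18.48,88.10
5,G,CIRC,RIMA to OM2,OM,41.81,1.76,74.95
5,G,RCA,Radial to PDA,PDA,22.77,2.65,66.68
5,H,LAD,LIMA to LAD,LAD,6.31,11.33,88.40
5,H,CIRC,RIMA to OM2,OM,57.54,1.21,74.82
5,H,RCA,RIMA to PDA,PDA,15.87,2.59,64.04
5,I,LAD,LIMA to LAD,LAD,24.47,2.98,90.80
5,I,CIRC,Radial to OM2,OM,37.41,1.97,70.56
5,I,RCA,RIMA to PDA,PDA,54.42,1.34,64.49
5,J,LAD,LIMA to LAD,LAD,24.47,2.98,90.80
5,J,CIRC,RIMA to OM2,OM,54.85,1.16,72.72
5,J,RCA,Radial to PDA,PDA,15.29,3.04,63.81
5,K,LAD,RIMA to LAD,LAD,18.02,4.17,86.77
5,K,CIRC,LIMA to OM2,OM,42.85,1.72,75.99
5,K,RCA,Radial to PDA,PDA,23.14,1.97,66.84
5,L,LAD,LIMA to LAD,LAD,23.83,3.05,92.09
5,L,CIRC,RIMA to OM2,OM,42.79,1.68,75.95
5,L,RCA,Radial to PDA,PDA,-2.99,9.80,56.71
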