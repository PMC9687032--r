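run_id,ethanol,time,temperature,power,DPPH,DPPH_sd,DPPH_rsm,DPPH_ann,ABTS,ABTS_sd,ABTS_rsm,ABTS_ann,TPC,TPC_sd,TPC_rsm,TPC_ann,TFC,TFC_sd,TFC_rsm,TFC_ann
1,70,4,140,600,18.94,2.98,20.34,19.30,37.14,0.54,38.87,37.08,33.88,0.62,33.77,33.45,17.67,0.16,18.15,17.68
2,50,3,130,150,26.13,3.12,25.84,25.15,28.30,2.13,28.51,28.20,25.40,0.62,25.78,25.51,10.61,0.44,9.67,9.96
3,30,2,110,300,20.95,1.12,19.89,21.13,36.25,1.87,34.58,36.20,29.55,0.17,29.80,29.51,12.89,0.65,13.36,12.90
4,50,3,130,450,25.75,2.98,26.79,25.62,40.83,1.35,41.80,41.61,36.02,2.15,35.58,35.44,14.49,0.16,14.03,14.47
5,10,3,130,450,17.42,1.29,19.86,20.49,29.00,2.34,31.46,28.96,22.29,0.17,23.68,23.76,10.61,0.33,9.61,10.60
6,90,3,130,450,7.31,1.61,6.39,6.43,25.36,1.77,23.30,26.08,21.50,1.24,20.81,21.49,9.23,0.42,8.45,9.33
7,50,3,130,450,26.13,2.35,26.79,25.62,41.83,1.35,41.80,41.61,35.05,0.79,35.58,35.44,13.49,0.95,14.03,14.47
8,50,3,90,450,14.76,1.64,16.51,15.45,30.37,1.51,31.39,30.26,21.44,1.37,21.26,21.60,7.50,0.75,7.50,7.51
9,30,4,110,300,23.39,2.41,21.79,23.45,34.01,2.07,34.03,34.68,30.55,0.75,28.52,29.96,11.61,0.88,11.42,11.60
10,30,4,140,300,20.76,2.32,21.00,20.18,29.40,3.70,28.78,29.39,20.48,1.72,21.83,20.88,7.45,0.65,8.40,7.44
11,50,3,130,750,27.63,2.61,29.44,28.90,42.61,0.63,42.80,42.49,35.99,0.52,36.31,36.85,18.95,0.44,18.11,18.90
12,70,2,140,600,19.58,2.20,19.53,19.64,34.20,2.40,34.47,32.69,26.99,2.25,28.54,26.76,16.85,0.36,17.82,17.13
13,30,2,140,600,29.21,2.60,29.48,28.40,42.29,2.38,40.85,42.16,30.94,0.17,29.27,30.85,16.65,0.38,17.60,17.45
14,30,4,140,600,32.59,1.12,29.20,31.87,39.39,3.39,39.50,39.31,31.44,1.64,30.23,31.59,13.19,1.10,13.90,13.18
15,70,2,110,300,13.97,2.03,15.08,13.22,25.61,2.02,25.61,25.66,20.74,2.03,21.51,20.74,6.44,1.01,6.47,6.46
16,50,3,130,450,27.25,1.75,26.79,25.62,41.83,1.35,41.80,41.61,36.08,0.34,35.58,35.44,13.49,0.58,14.03,14.47
17,50,5,130,450,27.71,2.62,28.68,29.97,38.89,1.59,37.40,38.84,28.55,1.20,27.74,28.67,12.45,0.98,11.80,12.43
18,70,4,140,300,16.77,2.11,17.89,15.43,28.19,1.90,29.89,28.21,23.41,0.12,23.44,23.56,9.24,0.45,9.96,9.32
19,30,2,140,300,30.79,3.26,31.07,30.40,32.37,1.35,31.97,32.25,25.23,1.30,23.89,27.72,11.82,0.65,12.54,11.78
20,70,2,110,600,11.96,2.20,11.85,11.66,27.48,0.97,27.40,24.64,22.63,0.60,21.06,22.61,6.94,0.74,7.00,8.54
21,70,4,110,300,18.51,0.79,18.08,19.66,30.64,1.78,30.82,30.56,23.41,0.89,24.49,25.33,8.43,0.68,8.55,8.43
22,30,2,110,600,24.84,1.20,22.39,27.18,38.94,1.05,38.11,38.90,27.56,1.64,27.43,27.64,11.21,0.77,11.21,11.21
23,50,1,130,450,29.42,2.33,29.96,27.75,32.54,1.60,34.43,32.56,22.55,0.62,24.06,22.56,15.28,0.36,14.15,15.28
24,70,4,110,600,26.77,1.15,24.64,26.70,34.49,2.10,34.44,32.63,26.55,0.37,27.06,25.76,9.42,0.12,9.54,9.44
25,30,4,110,600,32.74,1.55,34.09,32.34,39.87,1.16,39.39,40.81,27.88,1.26,29.18,28.04,9.52,0.45,9.71,9.72
26,50,3,150,450,27.71,2.30,26.24,27.96,39.33,0.64,37.81,39.19,27.67,0.66,28.95,27.73,15.35,0.64,15.97,15.38
27,70,2,140,300,27.44,1.44,28.85,27.89,27.36,2.30,27.33,27.32,22.80,0.76,21.24,22.72,9.23,0.39,10.08,9.31
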