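depth_m,nh4,no2,no3,po4,o2
5,0.08,0.10,0.30,0.20,210
30,0.06,0.70,1.50,0.35,195
50,0.05,0.40,8.00,0.80,150
75,0.05,0.20,14.00,1.30,60
100,0.05,0.10,18.00,1.70,8
150,0.05,0.05,20.00,1.95,4
200,0.05,0.08,21.50,2.10,12
250,0.05,0.12,22.50,2.20,16
300,0.05,0.33,24.50,2.40,1
400,0.05,0.33,25.00,2.45,0.8
500,0.05,0.30,26.00,2.50,0.7
600,0.05,0.25,27.50,2.55,0.9
700,0.04,0.15,30.00,2.65,1.5
800,0.04,0.08,33.00,2.70,4
900,0.04,0.05,35.00,2.80,9
1000,0.04,0.02,36.00,2.88,14
1200,0.04,0.02,38.00,3.00,19
1430,0.04,0.02,39.00,3.05,23
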