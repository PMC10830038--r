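bin,adult_migrant,adult_nonmigrant,nonadult_migrant,nonadult_nonmigrant
1,0.077,0.018,0.037,0.000
2,0.060,0.053,0.140,0.241
3,0.186,0.128,0.536,0.235
4,0.412,0.298,0.712,0.458
5,0.794,0.564,1.015,0.711
6,1.154,1.048,1.518,1.080
7,1.980,1.602,1.775,1.581
8,2.765,3.093,1.823,2.409
9,4.989,6.456,2.159,5.485
10,9.890,15.049,6.006,12.376
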