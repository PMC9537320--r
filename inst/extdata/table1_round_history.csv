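round,Accuracy_CST_AL,DATA_Count_CST_AL,Accuracy_CST,DATA_Count_CST,Accuracy_AL,DATA_Count_AL
1,0.83500,425,0.82250,425,0.80875,425
2,0.85000,1694,0.86000,1603,0.81375,828
3,0.86850,3298,0.85500,2719,0.83125,876
4,0.90125,4881,0.87250,3985,0.87375,1150
5,0.91000,6236,0.88625,5487,0.87750,1227
6,0.93125,7901,0.89125,7187,0.90000,1355
7,0.92875,8783,0.86875,8852,0.88000,1597
8,0.93750,10804,0.90125,10082,0.90750,1701
9,0.93625,11981,0.89375,11572,0.91875,1814
10,0.94000,13624,0.89750,13332,0.91375,1909
11,0.92875,14907,0.88750,15079,0.91750,1963
12,0.93250,16966,0.92250,16619,0.92125,2172
13,0.94125,19558,0.89500,18227,0.91125,2250
14,0.94750,21903,0.90875,19889,0.92000,2420
15,0.95375,23774,0.89375,21470,0.93000,2593
16,0.96000,26231,0.91375,23284,0.92250,2711
17,0.95875,31603,0.91750,25163,0.92000,2791
18,0.95750,33787,0.92000,26997,0.90875,2843
19,0.95625,36585,0.91500,28886,0.91875,2974
20,0.97500,38465,0.92625,30930,0.94000,3073
21,0.96625,40778,0.91750,32493,0.94125,3178
22,0.96875,43232,0.93750,34766,0.94125,3304
23,0.96125,45112,0.93000,36761,0.93250,3395
24,0.97250,46006,0.93750,38051,0.93000,3574
25,0.97625,47843,0.94375,40518,0.93500,3682
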