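# ion: C 12 (Z=6)
# medium: liquid water, density 1.0 g/cm^3
# model: Bethe electronic stopping with Barkas effective charge
# columns: energy_MeV_per_n LET_keV_per_um
0.05 205.2598
0.054023591 248.21811
0.058370968 289.74866
0.063068186 329.80966
0.068143398 368.36022
0.073627021 405.36059
0.079551922 440.77236
0.08595361 474.5587
0.092870454 506.68455
0.10034391 537.11696
0.10841877 565.82522
0.11714342 592.78123
0.12657017 617.95967
0.1367555 641.33833
0.14776046 662.89832
0.15965102 682.62435
0.17249842 700.505
0.18637969 716.53293
0.201378 730.70514
0.21758325 743.0232
0.23509257 753.49341
0.2540109 762.12705
0.27445162 768.94047
0.29653724 773.95528
0.32040014 777.1984
0.34618332 778.7022
0.37404132 778.50443
0.40414111 776.64832
0.43666308 773.18244
0.47180216 768.16064
0.50976893 761.64192
0.55079097 753.69019
0.59511412 744.37406
0.64300404 733.76656
0.69474775 721.94476
0.75065536 708.98938
0.81106197 694.98443
0.8763296 680.01663
0.94684944 664.17496
1.0230441 647.55012
1.1053704 630.23392
1.1943215 612.3187
1.2904308 593.89674
1.3942741 575.05961
1.5064739 555.8976
1.6277026 536.4991
1.7586868 516.95
1.9002115 497.33318
2.053125 477.72795
2.2183437 458.20959
2.3968578 438.84894
2.5897373 419.71202
2.7981382 400.8597
3.0233095 382.34752
3.2666007 364.22543
3.52947 346.53777
3.8134929 329.32317
4.1203717 312.61463
4.4519455 296.43957
4.8102016 280.82002
5.1972873 265.7728
5.6155225 251.3098
6.0674138 237.43828
6.5556697 224.16119
7.0832164 211.47755
7.6532157 199.38278
8.2690839 187.86917
8.9345122 176.92619
9.6534886 166.54094
10.430322 156.69849
11.26967 147.38225
12.17656 138.57433
13.15643 130.25584
14.215152 122.40721
15.359072 115.00841
16.595044 108.0392
17.930477 101.47938
19.373376 95.308892
20.932386 89.508025
22.616854 84.057504
24.436873 78.938603
26.403353 74.133211
28.528079 69.623891
30.823785 65.393917
33.304231 61.427293
35.984284 57.70877
38.880005 54.22384
42.008749 50.958728
45.38927 47.900383
49.041827 45.03645
52.988312 42.355252
57.252378 39.845766
61.859582 37.497589
66.837535 35.300917
72.216073 33.246512
78.027432 31.325677
84.306442 29.530225
91.090735 27.852457
98.420972 26.285134
106.34109 24.821448
114.89855 23.455007
124.14464 22.179804
134.13479 20.990198
144.92886 19.880897
156.59155 18.846934
169.19276 17.883647
182.80801 16.986667
197.5189 16.151897
213.41361 15.375498
230.58739 14.653872
249.14318 13.983649
269.19218 13.361673
290.85457 12.784988
314.26016 12.250828
339.54925 11.756605
366.8734 11.299894
396.39637 10.878428
428.29511 10.490083
462.7608 10.132874
500 9.8049391
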