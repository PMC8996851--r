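# ion: O 16 (Z=8)
# medium: liquid water, density 1.0 g/cm^3
# model: Bethe electronic stopping with Barkas effective charge
# columns: energy_MeV_per_n LET_keV_per_um
0.05 265.18812
0.054023591 321.45073
0.058370968 376.15607
0.063068186 429.25117
0.068143398 480.68332
0.073627021 530.40024
0.079551922 578.35028
0.08595361 624.48268
0.092870454 668.74775
0.10034391 711.09719
0.10841877 751.4843
0.11714342 789.86426
0.12657017 826.19445
0.1367555 860.4347
0.14776046 892.54765
0.15965102 922.49899
0.17249842 950.25785
0.18637969 975.79709
0.201378 999.0936
0.21758325 1020.1287
0.23509257 1038.8882
0.2540109 1055.3632
0.27445162 1069.5499
0.29653724 1081.4501
0.32040014 1091.0714
0.34618332 1098.4274
0.37404132 1103.5382
0.40414111 1106.4302
0.43666308 1107.1362
0.47180216 1105.696
0.50976893 1102.1561
0.55079097 1096.5695
0.59511412 1088.9962
0.64300404 1079.5027
0.69474775 1068.1619
0.75065536 1055.053
0.81106197 1040.2611
0.8763296 1023.8771
0.94684944 1005.997
1.0230441 986.72142
1.1053704 966.15548
1.1943215 944.40784
1.2904308 921.59025
1.3942741 897.81681
1.5064739 873.20333
1.6277026 847.86655
1.7586868 821.9234
1.9002115 795.4902
2.053125 768.68194
2.2183437 741.61148
2.3968578 714.38879
2.5897373 687.12026
2.7981382 659.90801
3.0233095 632.84923
3.2666007 606.03568
3.52947 579.5531
3.8134929 553.48084
4.1203717 527.8915
4.4519455 502.85062
4.8102016 478.41657
5.1972873 454.6404
5.6155225 431.56587
6.0674138 409.22953
6.5556697 387.66085
7.0832164 366.88248
7.6532157 346.91056
8.2690839 327.75505
8.9345122 309.42015
9.6534886 291.90477
10.430322 275.20298
11.26967 259.30453
12.17656 244.19533
13.15643 229.858
14.215152 216.27232
15.359072 203.41576
16.595044 191.2639
17.930477 179.79089
19.373376 168.96984
20.932386 158.77321
22.616854 149.17307
24.436873 140.14145
26.403353 131.65059
28.528079 123.6731
30.823785 116.18219
33.304231 109.15177
35.984284 102.55661
38.880005 96.372369
42.008749 90.575697
45.38927 85.144252
49.041827 80.056726
52.988312 75.292846
57.252378 70.83337
61.859582 66.660067
66.837535 62.755693
72.216073 59.103958
78.027432 55.68949
84.306442 52.497801
91.090735 49.515247
98.420972 46.728984
106.34109 44.126933
114.89855 41.697738
124.14464 39.430731
134.13479 37.31589
144.92886 35.343807
156.59155 33.505653
169.19276 31.793146
182.80801 30.198517
197.5189 28.714483
213.41361 27.334219
230.58739 26.051328
249.14318 24.859821
269.19218 23.754084
290.85457 22.728867
314.26016 21.77925
339.54925 20.90063
366.8734 20.0887
396.39637 19.339427
428.29511 18.649037
462.7608 18.013998
500 17.431003
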