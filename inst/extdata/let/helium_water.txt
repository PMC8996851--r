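# ion: He 4 (Z=2)
# medium: liquid water, density 1.0 g/cm^3
# model: Bethe electronic stopping with Barkas effective charge
# columns: energy_MeV_per_n LET_keV_per_um
0.05 67.396533
0.054023591 80.422548
0.058370968 92.599071
0.063068186 103.92434
0.068143398 114.39876
0.073627021 124.02494
0.079551922 132.80779
0.08595361 140.75461
0.092870454 147.87504
0.10034391 154.18117
0.10841877 159.68751
0.11714342 164.41098
0.12657017 168.37087
0.1367555 171.5888
0.14776046 174.08863
0.15965102 175.89637
0.17249842 177.04007
0.18637969 177.54967
0.201378 177.45682
0.21758325 176.79475
0.23509257 175.59802
0.2540109 173.90234
0.27445162 171.74431
0.29653724 169.16122
0.32040014 166.19077
0.34618332 162.87082
0.37404132 159.23916
0.40414111 155.33322
0.43666308 151.18986
0.47180216 146.84507
0.50976893 142.33383
0.55079097 137.68979
0.59511412 132.94518
0.64300404 128.13055
0.69474775 123.27469
0.75065536 118.40443
0.81106197 113.54461
0.8763296 108.71796
0.94684944 103.9451
1.0230441 99.244457
1.1053704 94.632349
1.1943215 90.122958
1.2904308 85.728417
1.3942741 81.458875
1.5064739 77.322596
1.6277026 73.326068
1.7586868 69.47412
1.9002115 65.770059
2.053125 62.215805
2.2183437 58.812029
2.3968578 55.558297
2.5897373 52.453207
2.7981382 49.494525
3.0233095 46.679314
3.2666007 44.004054
3.52947 41.464756
3.8134929 39.057064
4.1203717 36.776349
4.4519455 34.617791
4.8102016 32.576451
5.1972873 30.647334
5.6155225 28.825443
6.0674138 27.105821
6.5556697 25.483587
7.0832164 23.953969
7.6532157 22.51232
8.2690839 21.154139
8.9345122 19.875083
9.6534886 18.67097
10.430322 17.537792
11.26967 16.471708
12.17656 15.46905
13.15643 14.526319
14.215152 13.640182
15.359072 12.807465
16.595044 12.025156
17.930477 11.29039
19.373376 10.600451
20.932386 9.9527636
22.616854 9.3448864
24.436873 8.774508
26.403353 8.2394408
28.528079 7.7376149
30.823785 7.2670735
33.304231 6.8259672
35.984284 6.4125488
38.880005 6.0251688
42.008749 5.6622699
45.38927 5.3223833
49.041827 5.0041234
52.988312 4.7061841
57.252378 4.4273345
61.859582 4.166415
66.837535 3.9223337
72.216073 3.6940625
78.027432 3.4806339
84.306442 3.2811379
91.090735 3.0947185
98.420972 2.920571
106.34109 2.757939
114.89855 2.6061121
124.14464 2.4644227
134.13479 2.3322443
144.92886 2.2089886
156.59155 2.0941037
169.19276 1.9870719
182.80801 1.8874074
197.5189 1.7946553
213.41361 1.7083887
230.58739 1.628208
249.14318 1.5537388
269.19218 1.4846303
290.85457 1.4205542
314.26016 1.3612031
339.54925 1.3062894
366.8734 1.2555438
396.39637 1.2087142
428.29511 1.1655648
462.7608 1.1258749
500 1.0894377
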