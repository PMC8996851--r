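# ion: H 1 (Z=1)
# medium: liquid water, density 1.0 g/cm^3
# model: Bethe electronic stopping with Barkas effective charge
# columns: energy_MeV_per_n LET_keV_per_um
0.05 28.558757
0.054023591 33.65888
0.058370968 38.268636
0.063068186 42.400004
0.068143398 46.066344
0.073627021 49.282336
0.079551922 52.063906
0.08595361 54.428138
0.092870454 56.393176
0.10034391 57.978114
0.10841877 59.202873
0.11714342 60.088071
0.12657017 60.65489
0.1367555 60.924925
0.14776046 60.920046
0.15965102 60.66224
0.17249842 60.173467
0.18637969 59.475508
0.201378 58.589827
0.21758325 57.537429
0.23509257 56.338729
0.2540109 55.013441
0.27445162 53.580459
0.29653724 52.05777
0.32040014 50.462368
0.34618332 48.810189
0.37404132 47.116061
0.40414111 45.393662
0.43666308 43.655508
0.47180216 41.91294
0.50976893 40.176134
0.55079097 38.454125
0.59511412 36.754835
0.64300404 35.08512
0.69474775 33.450822
0.75065536 31.856829
0.81106197 30.307138
0.8763296 28.804926
0.94684944 27.352626
1.0230441 25.95199
1.1053704 24.604172
1.1943215 23.309793
1.2904308 22.069011
1.3942741 20.881584
1.5064739 19.746933
1.6277026 18.664197
1.7586868 17.632285
1.9002115 16.649917
2.053125 15.715674
2.2183437 14.828023
2.3968578 13.985359
2.5897373 13.18602
2.7981382 12.428319
3.0233095 11.710559
3.2666007 11.031047
3.52947 10.388108
3.8134929 9.780093
4.1203717 9.2053911
4.4519455 8.6624302
4.8102016 8.1496844
5.1972873 7.6656759
5.6155225 7.2089779
6.0674138 6.778215
6.5556697 6.3720647
7.0832164 5.9892567
7.6532157 5.6285734
8.2690839 5.2888487
8.9345122 4.9689673
9.6534886 4.6678638
10.430322 4.3845216
11.26967 4.1179709
12.17656 3.8672884
13.15643 3.6315947
14.215152 3.4100539
15.359072 3.2018711
16.595044 3.0062915
17.930477 2.8225989
19.373376 2.6501135
20.932386 2.4881913
22.616854 2.3362218
24.436873 2.1936271
26.403353 2.0598602
28.528079 1.9344037
30.823785 1.8167684
33.304231 1.7064918
35.984284 1.6031372
38.880005 1.5062922
42.008749 1.4155675
45.38927 1.3305958
49.041827 1.2510308
52.988312 1.176546
57.252378 1.1068336
61.859582 1.0416038
66.837535 0.98058342
72.216073 0.92351562
78.027432 0.87015848
84.306442 0.82028448
91.090735 0.77367963
98.420972 0.73014274
106.34109 0.68948475
114.89855 0.65152802
124.14464 0.61610568
134.13479 0.58306108
144.92886 0.55224716
156.59155 0.52352593
169.19276 0.49676796
182.80801 0.47185186
197.5189 0.44866382
213.41361 0.42709718
230.58739 0.40705201
249.14318 0.3884347
269.19218 0.37115757
290.85457 0.35513855
314.26016 0.34030078
339.54925 0.32657235
366.8734 0.31388594
396.39637 0.30217854
428.29511 0.2913912
462.7608 0.28146872
500 0.27235942
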