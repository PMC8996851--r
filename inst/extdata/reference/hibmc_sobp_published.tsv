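# Published comparison values for the HIBMC 320 MeV/n carbon-ion SOBP:
# biological dose (Gy) predicted by the NanOx and mMKM models at five
# depths, and RBE10 / RBE50 from both models together with the measured
# values of Kagawa et al. Inputs for relative-difference arithmetic.
depth_mm	dbio_nanox	dbio_mmkm	rbe10_kagawa	rbe10_nanox	rbe10_mmkm	rbe50_kagawa	rbe50_nanox	rbe50_mmkm
5	0.92	0.77	1.23	1.22	1.01	1.21	1.26	1.07
101	1.58	1.47	1.68	1.37	1.31	1.98	1.59	1.49
123	1.53	1.43	1.76	1.44	1.39	2.03	1.70	1.61
145	1.52	1.40	2.30	1.74	1.67	2.91	2.17	2.03
149	1.74	1.59	2.56	1.99	1.83	3.46	2.54	2.27
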