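# Synthetic chromophore absorption spectra (arbitrary units).
# These are NOT measured literature values: they are smooth analytic curves
# constructed to reproduce the qualitative near-infrared features of the four
# tissue chromophores (deoxyhemoglobin: high at 700 nm with a 760 nm shoulder,
# decaying; oxyhemoglobin: monotone rise beyond 800 nm; lipid: narrow 930 nm
# peak; water: 970 nm peak). Intended for simulation and testing only;
# substitute a measured compilation for quantitative work.
"wavelength_nm","hb","hbo2","water","lipid"
660,1.7076,0.3242,0.02,0.0304
665,1.6922,0.3277,0.02,0.0307
670,1.6709,0.3314,0.02,0.0311
675,1.6441,0.3354,0.02,0.0318
680,1.6122,0.3396,0.02,0.0329
685,1.5758,0.3441,0.02,0.0344
690,1.5358,0.3489,0.02,0.0366
695,1.4933,0.354,0.02,0.0396
700,1.4501,0.3594,0.02,0.0435
705,1.4079,0.3652,0.02,0.0486
710,1.3694,0.3712,0.02,0.0549
715,1.3368,0.3776,0.02,0.0625
720,1.3123,0.3843,0.02,0.0711
725,1.2971,0.3914,0.02,0.0806
730,1.2907,0.3987,0.02,0.0907
735,1.2904,0.4064,0.02,0.1007
740,1.2917,0.4145,0.02,0.1101
745,1.2884,0.4228,0.02,0.1182
750,1.2737,0.4315,0.02,0.1246
755,1.242,0.4404,0.02,0.1286
760,1.1898,0.4496,0.02,0.13
765,1.1172,0.4591,0.02,0.1286
770,1.0272,0.4688,0.02,0.1246
775,0.9259,0.4787,0.02,0.1182
780,0.8202,0.4887,0.02,0.1101
785,0.7172,0.4989,0.02,0.1007
790,0.6223,0.5092,0.02,0.0907
795,0.539,0.5196,0.02,0.0806
800,0.4686,0.53,0.02,0.0711
805,0.4108,0.5404,0.02,0.0625
810,0.3641,0.5508,0.02,0.0549
815,0.3264,0.5611,0.02,0.0486
820,0.2958,0.5713,0.0201,0.0435
825,0.2706,0.5813,0.0202,0.0396
830,0.2494,0.5912,0.0203,0.0366
835,0.2314,0.6009,0.0205,0.0344
840,0.2158,0.6104,0.0209,0.0329
845,0.2022,0.6196,0.0214,0.0318
850,0.1904,0.6285,0.0224,0.0312
855,0.18,0.6372,0.0238,0.0308
860,0.171,0.6455,0.0261,0.0308
865,0.1632,0.6536,0.0294,0.0314
870,0.1565,0.6613,0.0343,0.0332
875,0.1507,0.6686,0.0414,0.0376
880,0.1457,0.6757,0.0512,0.0469
885,0.1414,0.6824,0.0645,0.0652
890,0.1378,0.6888,0.0824,0.0977
895,0.1347,0.6948,0.1056,0.1508
900,0.1321,0.7006,0.135,0.2295
905,0.13,0.706,0.1715,0.3349
910,0.1281,0.7111,0.2156,0.4615
915,0.1266,0.7159,0.2673,0.5953
920,0.1254,0.7204,0.3264,0.7156
925,0.1243,0.7246,0.3919,0.7997
930,0.1235,0.7286,0.4624,0.83
935,0.1228,0.7323,0.5356,0.7997
940,0.1222,0.7358,0.6087,0.7156
945,0.1218,0.739,0.6786,0.5953
950,0.1214,0.7421,0.742,0.4615
955,0.1211,0.7449,0.7954,0.3349
960,0.1209,0.7475,0.836,0.2295
965,0.1207,0.75,0.8614,0.1508
970,0.1205,0.7522,0.87,0.0977
975,0.1204,0.7543,0.8614,0.0651
980,0.1203,0.7563,0.836,0.0469
985,0.1202,0.7581,0.7954,0.0375
990,0.1202,0.7598,0.742,0.0331
995,0.1201,0.7613,0.6786,0.0312
1000,0.1201,0.7628,0.6087,0.0304
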