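compound,A1,A2,A3,A4,B1,B2,B3,C1,C2,C3,C4,APA
N1,4.085,9.362,4.281,3.915,3.213,2.697,3.282,4.900,7.824,3.851,8.831,5.113
N2,4.245,10.777,4.368,3.945,3.818,3.170,3.055,4.497,9.414,4.117,10.525,5.630
N3,3.414,7.474,3.644,3.493,3.533,3.254,3.652,3.971,6.578,3.493,7.281,4.526
N4,3.567,8.805,3.731,3.560,3.278,3.038,3.481,4.041,7.506,3.508,8.386,4.809
N5,3.517,7.759,3.696,3.558,3.594,3.278,3.911,3.982,6.929,3.557,7.759,4.685
N6,3.674,9.155,3.785,3.600,3.558,3.249,3.739,4.011,8.023,3.635,9.012,5.040
N7,3.678,9.276,3.783,3.633,3.592,3.261,3.736,4.110,8.044,3.646,9.053,5.074
N8,3.834,10.614,3.872,3.665,3.526,3.186,3.567,4.067,9.171,3.711,10.338,5.414
N9,3.772,10.125,4.738,4.387,4.727,4.039,2.878,4.405,9.143,4.500,9.643,5.669
N10,3.931,11.553,4.825,4.416,3.462,2.898,2.950,4.368,9.469,4.211,10.740,5.711
N11,3.787,8.678,4.513,4.362,4.300,3.708,3.063,3.858,7.928,4.153,8.685,5.185
N12,3.948,10.130,4.599,4.402,4.330,3.754,2.886,3.936,9.029,4.248,9.979,5.567
N13,3.844,8.990,3.749,3.566,3.494,3.154,3.676,3.816,7.809,3.591,8.747,4.949
N14,3.624,8.496,4.364,4.291,4.113,3.561,3.233,3.668,7.546,3.974,8.492,5.033
N15,3.784,9.786,4.449,4.323,3.239,2.816,3.107,4.069,8.181,3.798,9.347,5.173
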