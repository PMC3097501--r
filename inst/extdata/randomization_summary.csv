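model,tool,mode,R2,R,Rr,Rr2,cRp2
A1,GFA-linear,process,0.889,0.943,0.531,0.282,0.735
A2,GFA-spline,process,0.919,0.959,0.533,0.284,0.764
A3,G/PLS-linear,process,0.856,0.925,0.669,0.448,0.591
A4,G/PLS-spline,process,0.906,0.952,0.808,0.653,0.479
B1,GFA-linear,process,0.824,0.908,0.467,0.218,0.707
B2,G/PLS-linear,process,0.839,0.916,0.671,0.450,0.571
B3,G/PLS-spline,process,0.865,0.930,0.778,0.605,0.474
C1,GFA-linear,process,0.935,0.967,0.646,0.417,0.696
C2,GFA-spline,process,0.925,0.962,0.715,0.511,0.619
C3,G/PLS-linear,process,0.883,0.940,0.686,0.471,0.603
C4,G/PLS-spline,process,0.919,0.959,0.795,0.632,0.514
A2,GFA-spline,model,0.919,0.959,0.379,0.144,0.844
A3,G/PLS-linear,model,0.856,0.925,0.058,0.003,0.854
A4,G/PLS-spline,model,0.906,0.952,0.120,0.014,0.899
C1,GFA-linear,model,0.935,0.967,0.368,0.135,0.865
C2,GFA-spline,model,0.925,0.962,0.377,0.142,0.851
C4,G/PLS-spline,model,0.919,0.959,0.113,0.013,0.913
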