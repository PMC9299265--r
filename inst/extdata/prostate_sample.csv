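Radius,Texture,Perimeter,Area,Smoothness,Compactness,Symmetry,Fractal_dimension,Diagnosis
23,12,151,954,0.143,0.278,0.242,0.079,M
9,13,133,1326,0.143,0.079,0.181,0.057,B
21,27,130,1203,0.125,0.16,0.207,0.06,M
14,16,78,386,0.07,0.284,0.26,0.097,M
9,19,135,1297,0.141,0.133,0.181,0.059,M
25,25,83,477,0.128,0.17,0.209,0.076,B
16,26,120,1040,0.095,0.109,0.179,0.057,M
15,18,90,578,0.119,0.165,0.22,0.075,M
19,24,88,520,0.127,0.193,0.235,0.074,M
25,11,84,476,0.119,0.24,0.203,0.082,M
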