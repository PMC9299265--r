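Radius,Texture,Perimeter,Area,Smoothness,Compactness,Concavity
20.57,17.77,132.90,1326.0,0.08,0.08,0.09
19.69,21.25,130.00,1203.0,0.11,0.16,0.20
20.29,14.34,135.10,1297.0,0.10,0.13,0.20
12.45,15.70,82.57,477.10,0.13,0.17,0.16
18.25,19.98,119.60,1040.0,0.09,0.11,0.11
13.71,20.83,90.20,577.90,0.12,0.16,0.09
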