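measure,elm_test_accuracy
Thickness,0.9114
Thickness STD,0.9048
Surface Area,0.8813
Volume,0.9063
Curvature,0.9238
WM,0.8956
Cortical GCOR,0.9057
SC Volume,0.8989
SC Intensity,0.8990
SC GCOR,0.9124
Overall Volume,0.9105
Group ICA,0.9295
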