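# creolegame transition stripe
# gamma=0.8 delta=0.1 N=2000 replicates=12 seed=20260901 epsilons=0.05,0.06,0.07
"x","y_lower","y_mid","y_upper"
0.01,0.48328125,0.52734375,0.55671875
0.02,0.49796875,0.54203125,0.57140625
0.05,0.55671875,0.60078125,0.63015625
0.1,0.65953125,0.68890625,0.70359375
0.2,0.77703125,0.79171875,0.79171875
0.3,0.83578125,0.85046875,0.85046875
0.4,0.87984375,0.87984375,0.87984375
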