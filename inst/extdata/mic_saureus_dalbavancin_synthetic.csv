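mic_mg_per_L,frequency
0.016,0.089
0.03,0.421
0.06,0.416
0.125,0.066
0.25,0.006
0.5,0.001
1,0.0005
2,0.0005
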