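time_h,c_in_g_per_m3
0,0.272
24,0.544
48,0.816
72,1.088
96,1.360
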