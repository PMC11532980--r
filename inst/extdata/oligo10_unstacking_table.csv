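temperature_C,dG_un_strand_a,dG_un_strand_b,f_stacked,dG_itc
10,1.62,1.65,1.0,-9.60
18,1.45,1.50,1.0,-9.76
25,1.30,1.37,0.97,-9.35
31,1.18,1.26,0.92,-8.82
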