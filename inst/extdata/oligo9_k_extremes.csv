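temperature_C,complex_conc_M,K
25,1.0e-5,6.1e4
25,1.5e-4,5.2e4
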