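"day","mean_diameter_um","std_um"
0,14,5.39
3,62.3336027613716,9.35004041420574
7,135.850020236529,20.3775030354793
10,191.392926936486,28.7089390404729
14,267.331197484088,40.0996796226131
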