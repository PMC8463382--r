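bond,R_nm,Kr
Fe_X-S_1,0.226,36024.2
Fe_X-S_2,0.227,35187.4
Fe_Y-S_1,0.230,30585.0
Fe_Y-S_2,0.231,29078.8
Fe_X-S_Cys1,0.240,23472.2
Fe_X-S_Cys2,0.240,23263.0
Fe_Y-S_Cys3,0.242,17572.8
Fe_Y-N_His,0.230,7740.4
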