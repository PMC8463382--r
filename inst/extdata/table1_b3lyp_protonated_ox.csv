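bond,R_nm,Kr
Fe_X-S_1,0.228,31254.5
Fe_X-S_2,0.229,29497.2
Fe_Y-S_1,0.221,46358.7
Fe_Y-S_2,0.221,45145.4
Fe_X-S_Cys1,0.232,33555.7
Fe_X-S_Cys2,0.232,33095.4
Fe_Y-S_Cys3,0.233,31882.1
Fe_Y-N_His,0.218,16359.4
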