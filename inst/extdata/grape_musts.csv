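code,sugar_g_L,nitrogen_mgN_L,malic_g_L,pH,total_SO2_mg_L,free_SO2_mg_L,active_SO2_mg_L
SB14,194,157,5.6,3.19,34,7,0.32
SB15,203,158,2.9,3.25,67,23,0.91
M14,207,111,2.1,3.58,37,29,0.54
M15,219,99,1.9,3.53,46,33,0.68
CS15,220,132,2.4,3.57,35,25,0.47
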