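run,coded_bt,coded_wc,coded_cdt,bt_c,wc_pct,cdt_a_c,cdt_b_c
1,-1,-1,0,110,55,70,60
2,1,-1,0,140,55,70,60
3,-1,1,0,110,65,70,60
4,1,1,0,140,65,70,60
5,-1,0,-1,110,60,60,55
6,1,0,-1,140,60,60,55
7,-1,0,1,110,60,80,65
8,1,0,1,140,60,80,65
9,0,-1,-1,125,55,60,55
10,0,1,-1,125,65,60,55
11,0,-1,1,125,55,80,65
12,0,1,1,125,65,80,65
13,0,0,0,125,60,70,60
14,0,0,0,125,60,70,60
15,0,0,0,125,60,70,60
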