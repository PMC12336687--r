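trial,bt_c,wc_pct,cdt_a_c,cdt_b_c,experimental,model,predicted,error_pct_printed
RSM,117,65,80,65,7.12,rsm,3.20,55.06
RSM,117,65,80,65,7.12,bo_init,6.11,14.19
RSM,117,65,80,65,7.12,bo_full,5.79,18.70
BO8,113,65,80,65,6.66,rsm,3.30,50.45
BO8,113,65,80,65,6.66,bo_init,6.08,8.71
BO12,121,65,80,65,7.46,rsm,3.33,55.36
BO12,121,65,80,65,7.46,bo_full,5.69,23.73
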