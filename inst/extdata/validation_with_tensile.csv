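trial,bt_c,wc_pct,cdt_a_c,cdt_b_c,experimental,model,predicted,error_pct_printed
RSM,115,65,80,65,14.54,rsm,5.67,61.00
RSM,115,65,80,65,14.54,bo_init,13.10,9.90
RSM,115,65,80,65,14.54,bo_full,10.98,24.48
BO7,110,65,80,65,11.60,rsm,6.48,44.14
BO7,110,65,80,65,11.60,bo_init,12.48,7.59
BO12,110,65,80,65,11.60,rsm,6.48,44.14
BO12,110,65,80,65,11.60,bo_full,10.36,10.69
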