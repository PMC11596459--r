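compound	rate_mmol_per_gdw_h	exchange_id
oxygen	18.5	EX_o2_e
glucose	11.7	EX_glc__D_e
L-threonine	0.48	EX_thr__L_e
succinate	0.95	EX_succ_e
glycine	0.1	EX_gly_e
cobalt2	0.0375	EX_cobalt2_e
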