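# Industrial-fermentation benchmark: P. denitrificans SC510, 7-day (168 h)
# fed-batch on sucrose/betaine/DMB medium, pH 7.15-7.30.
strain: Pseudomonas denitrificans SC510
product: vitamin B12 (as cyanocobalamin)
product_conc_mg_per_l: 214
duration_h: 168
dcw_g_per_l: 33.23
molar_mass_g_per_mol: 1355.37
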