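intervention	ec_numbers	b12_umol
none (curated model)	-	0.359
aminopropanol_linker	2.7.1.177, 4.1.1.81	0.400
ala_synthase	2.3.1.37	0.394
ala_synthase+gly_acetyltransferase	2.3.1.37, 2.3.1.29	0.394
aminopropanol_linker+ala_synthase	2.7.1.177, 4.1.1.81, 2.3.1.37	0.215
thr_dehydrogenase	1.1.1.103	0.230
gly_acetyltransferase	2.3.1.29	0.180
thr_dehydrogenase+gly_acetyltransferase	1.1.1.103, 2.3.1.29	0.391
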