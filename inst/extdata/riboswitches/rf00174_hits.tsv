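riboswitch	length_nt	genome_position	rfam_accession
1	207	2768769-2768976	RF00174
2	222	3857546-3857768	RF00174
3	197	2765029-2765226	RF00174
4	205	398802-3982007	RF00174
5	220	1866938-1867158	RF00174
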