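# Knockin / curation reaction bundles for the cobalamin pathway.
# Stoichiometries follow the KEGG reaction entries recorded under `source`;
# cofactor usage is simplified where KEGG lists alternatives. These are data,
# not code: amend formulas here without touching the engine.
bundles:
  base_curation:
    description: >
      Cobalamin-pathway reactions present in the P. putida KT2440 genome but
      missing from (or unnamed in) the iJN1463 reconstruction.
    reactions:
      - id: CBIACDAMS
        ec: 6.3.5.9
        name: cobyrinate a,c-diamide synthase
        source: KEGG R07772
        formula: "cbyr_c + 2 gln__L_c + 2 atp_c + 2 h2o_c -> cbyrcdam_c + 2 glu__L_c + 2 adp_c + 2 pi_c + 2 h_c"
        reversible: false
      - id: DMBZS_AER
        ec: 1.13.11.79
        name: aerobic 5,6-dimethylbenzimidazole synthase
        source: KEGG R09083
        formula: "fmnh2_c + o2_c -> dmbzid_c + e4p_c + h2o_c"
        reversible: false
      - id: PC3BS
        ec: 1.14.13.83
        name: precorrin-3B synthase
        source: KEGG R05224
        formula: "pre3a_c + nadh_c + h_c + o2_c -> pre3b_c + nad_c + h2o_c"
        reversible: false
  aminopropanol_linker:
    description: >
      Two-reaction aminopropanol linker route (PduX/CobD) turning L-threonine
      into the (R)-1-aminopropan-2-yl phosphate arm of cobalamin; absent from
      both Pseudomonas species.
    reactions:
      - id: THRK
        ec: 2.7.1.177
        name: L-threonine kinase
        source: KEGG R08211
        formula: "atp_c + thr__L_c -> adp_c + thrp_c + h_c"
        reversible: false
      - id: THRPDC
        ec: 4.1.1.81
        name: L-threonine-O-3-phosphate decarboxylase
        source: KEGG R05223
        formula: "thrp_c + h_c -> apropp_c + co2_c"
        reversible: false
  ala_synthase:
    description: >
      5-aminolevulinate synthase of the C4 pathway (glycine + succinyl-CoA),
      the route P. putida lacks natively.
    reactions:
      - id: ALAS_C4
        ec: 2.3.1.37
        name: 5-aminolevulinate synthase
        source: KEGG R00830
        formula: "succoa_c + gly_c -> 5aop_c + coa_c + co2_c"
        reversible: false
  thr_dehydrogenase:
    description: >
      L-threonine 3-dehydrogenase, boosting 2-amino-3-oxobutanoate supply
      from threonine.
    reactions:
      - id: THRD
        ec: 1.1.1.103
        name: L-threonine 3-dehydrogenase
        source: KEGG R01465
        formula: "thr__L_c + nad_c -> 2aobut_c + nadh_c + h_c"
        reversible: false
  gly_acetyltransferase:
    description: >
      Glycine C-acetyltransferase linking glycine and 2-amino-3-oxobutanoate
      pools.
    reactions:
      - id: GLYAT
        ec: 2.3.1.29
        name: glycine C-acetyltransferase
        source: KEGG R00371
        formula: "accoa_c + gly_c <-> coa_c + 2aobut_c"
        reversible: true
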