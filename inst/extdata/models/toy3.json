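{
  "id": "toy3",
  "metabolites": [
    {"id": "a_c", "name": "precursor", "compartment": "c"},
    {"id": "b_c", "name": "product", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_a_c", "name": "uptake", "metabolites": {"a_c": -1},
     "lower_bound": -10, "upper_bound": 1000,
     "gene_reaction_rule": "", "objective_coefficient": 0},
    {"id": "CONV", "name": "conversion", "metabolites": {"a_c": -1, "b_c": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "", "objective_coefficient": 0,
     "annotation": {"ec-code": ["1.4.4.2"]}},
    {"id": "EX_b_c", "name": "export", "metabolites": {"b_c": -1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "", "objective_coefficient": 1}
  ],
  "genes": [],
  "compartments": {"c": "cytosol"},
  "version": "1"
}
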