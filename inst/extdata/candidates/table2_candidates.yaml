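# Deletion candidates of the porphyrin-pathway screen. Compound EC entries
# (hyphen/slash separated) are alternative annotations of one candidate slot.
candidates:
  - label: Coproporphyrinogen oxidase
    ec: 1.3.3.3
  - label: Protoporphyrinogen oxidase (aerobic)
    ec: 1.3.3.4
  - label: Oxygen-independent coproporphyrinogen III dehydrogenase
    ec: 1.3.98.3-1.3.99.22
  - label: Uroporphyrinogen decarboxylase (uroporphyrinogen III)
    ec: 4.1.1.37
  - label: Sirohydrochlorin ferrochelatase
    ec: 4.99.1.4
  - label: Ferrochelatase
    ec: 4.99.1.1
  - label: Glycine cleavage system
    ec: 1.4.4.2
  - label: Tetrahydrofolate aminomethyltransferase
    ec: 2.1.2.10
  - label: Aminomethyltransferase
    ec: 2.1.2.10
  - label: 2-Oxoglutarate dehydrogenase
    ec: 1.8.1.4-1.2.4.2
  - label: L-allo-threonine dehydrogenase
    ec: 1.1.1.381
  - label: Sirohydrochlorin dehydrogenase (NAD)
    ec: 1.3.1.76
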