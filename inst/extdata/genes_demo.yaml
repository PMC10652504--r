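# Demo gene-context table.  One entry per gene symbol; fields follow the
# gene_context() arguments.  Per-gene threshold overrides stand in for
# gene-specific curated recommendation tables.
DEMOAD1:
  inheritance: AD
  category: general
  clinical_validity: definitive
  pli: 0.98
DEMOAR1:
  inheritance: AR
  category: general
  clinical_validity: strong
  complete_penetrance: true
DEMOCAN1:
  inheritance: AD
  category: cancer
  clinical_validity: definitive
DEMOVCEP1:
  inheritance: AD
  category: cancer
  clinical_validity: definitive
  vcep_curated: true
DEMOOVR1:
  inheritance: AD
  category: general
  clinical_validity: limited
  frequency_overrides:
    ba1: 0.05
    bs1_s: 0.002
    pm2_p: 0.00002
    pm2_m: ~        # absent required
  insilico_overrides:
    revel_pp3: 0.6
    revel_bp4: 0.3
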