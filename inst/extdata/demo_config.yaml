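# Demo run: small simulated cohort, analysed end to end.
sim:
  nFamilies: 12
  readDepth: 8000
  seed: 7
minReads: 5000
minSamples: 2
rarefy: true
metric: bray_curtis
basis: membership
relations:
  - mother_child
groups:
  - combined
B: 200
seed: 7
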