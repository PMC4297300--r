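# Example pipeline configuration: small synthetic run with all stages.
seed: 42
stages: [cluster, diff, motif]
diff_B: 999
top_n: 20
sim:
  n_ligands: 150
  seed: 42
nn:
  epochs: 60
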