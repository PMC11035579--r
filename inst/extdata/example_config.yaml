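# Example pipeline configuration (synthetic end-to-end run).
seed: 1
stages:
  simulate: true
  annotate: true
  clonotype: true
  diversity: true
  rescue: false
  phenotype: false
paths:
  reference: ~        # default synthetic reference when unset
  out_dir: tcr_out
simulation:
  n_cells: 500
  clonality_profile: oligoclonal
diversity:
  n_target: 400
  n_perm: 50
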