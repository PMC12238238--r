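seed: 42
simulate:
  pangenome:
    n_positive: 3
    n_negative: 3
    n_decoys: 6
    family_length: 200
    divergence: 0.15
    n_marker_proximal: 2
  metagenome:
    groups:
      female: 12
      male: 12
    carriage_a: 0.9
    carriage_b: 0.5
    depth: 20000
    read_length: 150
    error_prob: 0.005
screen:
  min_bits: 50
profile:
  min_len: 150
  null_n: 200
metaprofile:
  qc_min_reads: 10000
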