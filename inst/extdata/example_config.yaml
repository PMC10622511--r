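genome:
  chr_v_len: 200000
  donor_len: 100000
  ballast_lens: []
  ho_site: no
  seed: 507244245
foldback:
  event_weights:
    foldback: 0.7
    nhej: 0.2
    homeologous_gc: 0.1
  ir_lambda: 200.0
  max_flap: 600.0
  ir_candidates:
  - IR_target
  - IR_alt_tel
  - IR_alt_cen
  correct_mismatches: yes
  break_window:
  - 5000.0
  - 30000.0
  stabilization_weights:
    repeat_translocation: 0.5
    centromere_deletion: 0.2
    telomere_addition: 0.3
  element_choice: random
  cen_del_flank_range:
  - 1000.0
  - 150000.0
  seed: 507259965
reads:
  depth: 30.0
  read_len: 75
  frag_mean: 300.0
  frag_sd: 30.0
  error_rate: 0.0
  seed: 507159357
cnv:
  bin_width: 5000
  pseudocount: 0.0625
  alpha: 0.001
  n_null_splits: 10
  pool: genome
  min_bin_fraction: 0.5
  seed: 507040278
screen:
  gain_threshold: 1.5
  e_target: 2.0
  e_ref: 2.0
  cq_noise_sd: 0.0
  max_product: 5000
  seed: 507243459
n_clones: 5
seed: 1
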