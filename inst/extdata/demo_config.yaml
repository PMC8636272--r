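# Bundled demo configuration: a small, fully synthetic end-to-end run.
# Every key is optional; omitted keys fall back to the package defaults
# (these values restate them explicitly for documentation).
seed: 42
outdir: sedapipe_run
taxonomy:
  n_families: 3
  genera_per_family: 2
  species_per_genus: 2
reference:
  genome_length: 800
  divergence: 0.08
samples:
  n_samples: 10
  reads_per_sample: 200
  age_min: 1000
  age_max: 19000
controls:
  reads_per_control: 60
fragment:
  mean_len: 55
  sd_len: 12
  min_len: 30
  max_len: 120
damage:
  p1_ct: 0.25
  lambda_decay: 0.3
  seq_error: 0.001
classify:
  rank: genus
  min_reads: 3
  min_samples: 1
abundance:
  n_sim: 500
community:
  bin_width: 2000
  nmds_k: 2
  nmds_starts: 20
  nmds_method: bray
placement:
  enabled: true
  n_tips: 6
  mutations_per_branch: 4
  genome_length: 3000
  coverage: 4
  mode: all-sites
  min_markers: 10
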