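# Demo pipeline configuration: a small congeneric series (12 neutral
# compounds in subgroups 0/1/14 plus 2 charged), a 5-replica ESMACS
# ensemble of 25 frames per compound, and an 8-edge two-hub TI network
# with 5 replicas per window. Sized to run in seconds.
seed: 42
temperature: 300
bootstrap_B: 1000
out_dir: enfea-demo
series:
  subgroup_sizes: {"0": 1, "1": 6, "14": 5}
  pic50_range: [5.03, 8.37]
  n_charged: 2
  n_censored: 1
  planted_r: 0.9
esmacs:
  n_replicas: 5
  n_frames: 25
  protocol: 1traj
  between_replica_sd: 1.0
ti:
  n_edges: 8
  n_dual: 2
  n_replicas: 5
  n_samples_per_window: 50
  within_replica_sd: 0.3
  between_replica_sd: 0.2
network:
  hubs: [L30, L2]
  offset: fit
  flag_threshold: 0.5
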