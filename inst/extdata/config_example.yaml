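# Example pipeline configuration. Every analysis constant is a named key;
# values shown are the defaults.
low_hz: 0.0025          # bandpass lower edge (Hz)
high_hz: 0.05           # bandpass upper edge (Hz)
filter_order: 4         # Butterworth order of the zero-phase filter
fixation_threshold: 0.85 # runs with fixation fraction below this are excluded
k_min: 2                # smallest cluster solution examined
k_max: 10               # largest cluster solution examined
n_perm: 100000          # fingerprint permutation iterations (exact enumeration
                        # substitutes automatically when 2^subjects <= n_perm)
alpha: 0.05             # pairwise fingerprint significance level
z_threshold: 2.3        # seed-to-brain map threshold (strict >)
seed_radius_mm: 2       # seed sphere radius
hrf_kind: MION          # MION (contrast agent, sign-inverted) or BOLD
rng_seed: 1
synthetic:
  n_voxels: 100
  k_true: 4
  n_seeds: 23
  n_subjects: 8
  n_runs_per_subject: 3
  n_volumes: 300
  tr_seconds: 2
  community_snr: 2
  nuisance_amplitude: 0.5
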