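{
  "seed": 7,
  "simulate": {
    "n_tracks": 2,
    "behavior": {
      "stage_durations": [90, 70, 70, 120],
      "bout_durations": [20, 20, 20],
      "hatch_delay": 30
    },
    "expression": {
      "n_individuals": 60,
      "stage_span": 600,
      "n_genes_per_archetype": 10,
      "dispersion": 0.1,
      "jitter_sd": 0.1
    }
  },
  "stage": {"threshold_frac": 0.1, "min_duration_min": 10, "merge_gap_min": 5},
  "filter": {"min_reads": 7, "min_fraction": 0.3},
  "reconstruct": {"cutoff_min": 5, "embed": false},
  "pool": {"window_min": 30},
  "cluster": {"preset": "profiles", "k": 8}
}
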