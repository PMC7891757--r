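{
  "per_recording_required": [
    "id", "n_dwells", "mean_dwell_time", "outside_share",
    "matrix_density", "gte", "lzc", "k", "k_scope", "rmse", "omissions"
  ],
  "group_required": ["group", "n_recordings", "common_ngrams"],
  "provenance_required": ["package_version", "seed", "config_hash"]
}
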