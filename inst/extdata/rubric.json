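{
  "profile": "salisbury-tsourkas-2019",
  "min_orf_len": 76,
  "start_codons": ["ATG", "GTG", "TTG"],
  "coding_high": 0.75,
  "coding_sustain": 0.5,
  "coding_low": 0.25,
  "sim_sig": 1e-10,
  "sim_mid": 1e-20,
  "sim_strong": 1e-50,
  "overlap_bins": [10, 40, 70, 100],
  "operon_overlaps": [1, 4, 8],
  "divergent_gap": 50,
  "length_bins": [90, 120, 150, 200],
  "keep_thresh": 3,
  "discard_thresh": 0,
  "large_overlap": 100,
  "sd_tie_tol": 0.1,
  "anchor_programs": []
}
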