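{
  "description": "Barcode-gap partition of a 12-record, 3-cluster toy set (p-distance; intraspecific <= 0.10 via a hub record, interspecific >= 0.40; brute-force single-linkage components confirm 3 clusters at any threshold between 0.10 and 0.40).",
  "model": "simple",
  "p_min": 0.001,
  "p_max": 0.1,
  "steps": 10,
  "X": 1.5,
  "n_groups": 3,
  "tags": ["TRUE", "TRUE", "TRUE"],
  "true_species_pct": 100
}
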