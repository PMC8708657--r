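{
  "description": "Best Match outcomes on a 5-record, 3-species toy set (hand-enumerated): BK001-BK004 find conspecific nearest neighbours; the singleton BK005 ties two allospecific records at p = 0.5 and is Incorrect.",
  "criterion": "BM",
  "per_record": {
    "BK001": "Correct",
    "BK002": "Correct",
    "BK003": "Correct",
    "BK004": "Correct",
    "BK005": "Incorrect"
  },
  "pct_correct": 80,
  "pct_incorrect": 20,
  "pct_ambiguous": 0,
  "pct_nomatch": 0,
  "species_correct_pct": 66.66666666666667,
  "true_species_pct": 66.66666666666667
}
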