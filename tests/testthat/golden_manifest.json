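{
  "features_tested": {
    "mRNA": 55,
    "miRNA": 25,
    "lncRNA": 25
  },
  "de_calls": {
    "mRNA": 11,
    "miRNA": 10,
    "lncRNA": 10
  },
  "kept_after_reference_filter": {
    "mRNA": 8,
    "miRNA": 8,
    "lncRNA": 8
  },
  "pairs_computed": {
    "mm": 64,
    "ml": 64,
    "lm": 64
  },
  "pairs_thresholded": {
    "mm": 34,
    "ml": 63,
    "lm": 33
  },
  "pairs_predicted": {
    "mm": 5,
    "ml": 13
  },
  "triads": 3,
  "dm_calls": 3,
  "quadrant_counts": {
    "1": 0,
    "2": 2,
    "3": 1,
    "4": 3,
    "5": 42,
    "6": 7,
    "7": 0,
    "8": 0,
    "9": 0
  },
  "hypo_up_genes": 1,
  "enriched_sets": "NA"
}
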