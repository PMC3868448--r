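{
  "comment": "SYNTHETIC diagnostic rules for the synthetic amplicons built by the test helpers; real assay motifs are lab-specific and are not modelled.",
  "site1011": {"type": "motif", "Ile": "CATATTACG", "Met": "CATATGACG"},
  "intron": {"type": "length", "threshold": 60, "ge": "B", "lt": "A"},
  "site1016": {"type": "motif", "Val": "TTGGTATCC", "Ile": "TTGATTTCC"}
}
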