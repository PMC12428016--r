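{
  "genome_length_bp": 17504,
  "whole_genome_pct": {"A": 32.32, "T": 24.41, "C": 12.84, "G": 30.42},
  "whole_genome_reported": {"at_skew": 0.13, "gc_skew": -0.40},
  "rrna_pct": {"A": 35.63, "T": 21.12, "C": 25.98, "G": 17.27},
  "control_region_pct": {"A": 33.55, "T": 29.92, "C": 24.30, "G": 12.24},
  "pcg_reported": {"total_length_bp": 11444, "total_codons": 3811, "enc": 57.65, "at_content_pct": 57.0},
  "trna_length_range_reported": [67, 75]
}
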