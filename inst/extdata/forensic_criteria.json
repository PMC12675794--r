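{
  "transverse": {
    "min_lines": 1, "max_lines": 1,
    "min_length": 0.9, "max_length": 1.6,
    "min_fragments": 2, "max_fragments": 2,
    "max_extent": 15
  },
  "oblique": {
    "min_lines": 1, "max_lines": 1,
    "min_length": 1.0, "max_length": 3.0,
    "min_fragments": 2, "max_fragments": 2,
    "max_extent": 60
  },
  "spiral": {
    "min_lines": 1, "max_lines": 1,
    "min_length": 1.2, "max_length": 4.0,
    "min_fragments": 2, "max_fragments": 2,
    "max_extent": 80
  },
  "wedge": {
    "min_lines": 2, "max_lines": 2,
    "min_length": 1.2, "max_length": 2.5,
    "min_fragments": 3, "max_fragments": 3,
    "max_extent": 25
  },
  "comminuted": {
    "min_lines": 3, "max_lines": 13,
    "min_length": 1.2, "max_length": 8.0,
    "min_fragments": 3, "max_fragments": 15,
    "max_extent": 40
  }
}
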