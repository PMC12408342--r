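[
  {
    "steps": 1,
    "lzw_reachable_length": 1,
    "assembly_reachable_length": 2
  },
  {
    "steps": 2,
    "lzw_reachable_length": 3,
    "assembly_reachable_length": 4
  },
  {
    "steps": 3,
    "lzw_reachable_length": 6,
    "assembly_reachable_length": 8
  },
  {
    "steps": 4,
    "lzw_reachable_length": 10,
    "assembly_reachable_length": 16
  }
]
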