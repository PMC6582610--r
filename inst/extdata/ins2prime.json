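{
  "name": "ins2prime",
  "a": [5, 6, 6, 7, 7, 17],
  "b": [3, 5, 6, 6, 7, 21],
  "c": [1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 16]
}
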