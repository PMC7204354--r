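{
  "X4": 1,
  "X21": 2,
  "X24": 3,
  "X184": 4,
  "X185": 2,
  "X209": 4,
  "X229": 2,
  "X230": 2,
  "X207": 0,
  "X208": 0,
  "X236": 0
}
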