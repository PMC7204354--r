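{
  "X4": 1,
  "X21": 2,
  "X24": 3,
  "X184": 4,
  "X185": 2,
  "X207": 0,
  "X208": 0,
  "X209": 3,
  "X222": 3,
  "X223": 1,
  "X224": 1,
  "X225": 1,
  "X226": 1,
  "X236": 0
}
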